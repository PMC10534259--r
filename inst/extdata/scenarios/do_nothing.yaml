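# Comparator: no tax, no implementation cost.
name: do_nothing
rate_per_litre: 0
included_categories: []
pass_through: 1.0
mean_price: 45.05
implementation_cost_multiplier: 0
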