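# Proposed tax base (coffee included) at the implemented rate.
name: scenario_a
rate_per_litre: 6
included_categories: [soft_drinks, energy_sports_drinks, juice, sweetened_tea,
  powdered, cereal_grain, coffee_based, other]
pass_through: 1.0
mean_price: 45.05
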