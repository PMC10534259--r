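# Best case: coffee- and milk-based beverages included, 10/litre.
name: scenario_c
rate_per_litre: 10
included_categories: [soft_drinks, energy_sports_drinks, juice, sweetened_tea,
  powdered, cereal_grain, coffee_based, milk_based, other]
pass_through: 1.0
mean_price: 45.05
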