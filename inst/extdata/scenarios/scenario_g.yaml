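# Implemented design with child overweight/obesity utility weights taken
# from the alternative (review-derived) set.
name: scenario_g
rate_per_litre: 6
included_categories: [soft_drinks, energy_sports_drinks, juice, sweetened_tea,
  powdered, cereal_grain, other]
pass_through: 1.0
mean_price: 45.05
child_utility_set: review
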