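# Small additive value set used for hand-checkable tests: 0.10 off for any
# problem, 0.05 per dimension at level 2, 0.15 per dimension at level 3.
# Worst state (33333) scores 1 - 0.10 - 5*0.15 = 0.15.
name: toy_linear
description: Toy additive value set for testing
constant_any_problem: 0.10
any_level3: 0.0
decrements:
  mobility:           {level2: 0.05, level3: 0.15}
  self_care:          {level2: 0.05, level3: 0.15}
  usual_activities:   {level2: 0.05, level3: 0.15}
  pain_discomfort:    {level2: 0.05, level3: 0.15}
  anxiety_depression: {level2: 0.05, level3: 0.15}
minimum: 0.15
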