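# Dutch EQ-5D-3L time trade-off tariff (Lamers LM et al., Ned Tijdschr
# Geneeskd 2005 / Health Econ 2006). Utility = 1 minus a constant term for
# any problem, minus per-dimension level decrements, minus an extra term
# when any dimension is at level 3. Worst state (33333) scores -0.329.
name: dutch_tariff_3l
description: Dutch EQ-5D-3L TTO value set (Lamers et al. 2006)
constant_any_problem: 0.071
any_level3: 0.234
decrements:
  mobility:           {level2: 0.036, level3: 0.161}
  self_care:          {level2: 0.082, level3: 0.152}
  usual_activities:   {level2: 0.032, level3: 0.057}
  pain_discomfort:    {level2: 0.086, level3: 0.329}
  anxiety_depression: {level2: 0.124, level3: 0.325}
minimum: -0.329
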