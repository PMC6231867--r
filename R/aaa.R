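# Shared constants (file sorts first so top-level code in other files can
# use them at load time).

# The five EQ-5D-3L dimensions, in questionnaire order.
eq5d_dimensions <- c(
  "mobility", "self_care", "usual_activities",
  "pain_discomfort", "anxiety_depression"
)

arm_levels <- c("control", "intervention")
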