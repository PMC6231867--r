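# Default configuration for the cost-utility pipeline.
#
# Unit prices, travel distances and intervention-cost inputs are a documented
# EXAMPLE tariff in 2015 euros, chosen to be of realistic Dutch magnitude;
# they are config-driven and meant to be replaced with an authoritative
# costing manual for real analyses. The `simulate` section calibrates the
# synthetic cohort generator: arm sizes, utility trajectories, dropout
# hazards, employment and per-category annual cost means are the study
# conditions the generator reproduces in expectation.

value_set: dutch_tariff_3l
wave_months: [0, 6, 9, 12, 15, 18]
cost_wave_months: [9, 12, 15, 18]   # recall windows covering the follow-up year
qaly_horizon_months: [6, 18]        # 1-year QALY window, post-intervention onward
price_year: 2015

prices:                # euro per contact / admission / day
  rheumatologist: 91
  rheumatology_nurse: 40
  occupational_therapist: 40
  physical_therapist: 40
  podiatrist: 35
  hydrotherapist: 40
  daycare_admission: 280
  inpatient_day: 480
  rehabilitation_day: 460
  general_practitioner: 33
  occupational_health_doctor: 75
  psychological_care: 90
  alternative_medicine: 55

medication_prices:     # euro per dose unit (one unit/day at standard dose)
  painkiller: 0.10
  nsaid: 0.15
  dmard: 1.50
  corticosteroid: 0.30
  biologic: 68.00
  mental_health: 0.40
  sleep: 0.30

travel:
  km_rate: 0.19        # euro per kilometre
  distances:           # round-trip km per contact
    rheumatologist: 28
    rheumatology_nurse: 28
    occupational_therapist: 28
    physical_therapist: 6
    podiatrist: 6
    hydrotherapist: 12
    daycare_admission: 28
    inpatient_day: 28
    rehabilitation_day: 28
    general_practitioner: 3.4
    occupational_health_doctor: 20
    psychological_care: 20
    alternative_medicine: 20

friction:
  friction_period_weeks: 12
  vacancy_extension_weeks: 4
  cost_per_hour: 34.90

intervention_model:
  development_cost: 150000       # incl. updating and security costs
  amortization_years: 5
  prevalence_count: 260000       # national RA population
  eligible_fraction: 0.30        # share with elevated distress
  reach_fraction: 0.10           # assumed population reach
  therapist_rate_basic: 75       # euro/hour
  therapist_rate_postacademic: 95
  assistant_rate: 36             # euro/hour, website-introduction call
  assistant_session_minutes: 30
  km_rate: 0.19                  # intake travel

analysis:
  bootstrap_replications: 1000
  percentiles: [2.5, 97.5]
  wtp_max: 100000
  wtp_step: 1000
  exclude: []

simulate:
  n_control: 71
  n_intervention: 62
  female_fraction: 0.639
  age: {mean: 56.35, sd: 10.0, min: 26, max: 81}
  utility:
    # latent truncated-normal utility means per wave (baseline, then the
    # post-intervention and four quarterly follow-up waves), snapped to the
    # nearest achievable EQ-5D-3L state under the active value set
    mean:
      control:      [0.69, 0.80, 0.80, 0.80, 0.80, 0.80]
      intervention: [0.74, 0.86, 0.86, 0.86, 0.86, 0.86]
    sd_baseline: {control: 0.23, intervention: 0.19}
    sd_followup: 0.18
    within_patient_correlation: 0.7
  dropout_hazard:
    # per-wave Bernoulli hazard after baseline; (1 - h)^5 gives the
    # all-waves completer fractions 0.42 (control) and 0.27 (intervention)
    control: 0.159455
    intervention: 0.230324
  employment:
    fraction: 0.434
    contracted_hours: [16, 24, 32, 40]
  healthcare_annual_euro:
    # expected annual euros per category per arm (counts are derived by
    # dividing by the unit price); heavy tails via lognormal patient rates
    control:
      rheumatologist: 364
      rheumatology_nurse: 120
      occupational_therapist: 40
      physical_therapist: 480
      podiatrist: 70
      hydrotherapist: 80
      daycare_admission: 280
      inpatient_day: 480
      rehabilitation_day: 230
      general_practitioner: 132
      occupational_health_doctor: 75
      psychological_care: 90
      alternative_medicine: 107
    intervention:
      rheumatologist: 364
      rheumatology_nurse: 120
      occupational_therapist: 40
      physical_therapist: 560
      podiatrist: 70
      hydrotherapist: 80
      daycare_admission: 280
      inpatient_day: 720
      rehabilitation_day: 230
      general_practitioner: 132
      occupational_health_doctor: 75
      psychological_care: 470
      alternative_medicine: 111
  healthcare_zero_fraction: 0.4   # point mass at zero users per category
  healthcare_sdlog: 1.0           # lognormal dispersion of patient rates
  medication:
    user_fraction:
      control:      {painkiller: 0.125, nsaid: 0.453, dmard: 0.8125,
                     corticosteroid: 0.203, biologic: 0.328,
                     mental_health: 0.094, sleep: 0.10}
      intervention: {painkiller: 0.179, nsaid: 0.411, dmard: 0.821,
                     corticosteroid: 0.214, biologic: 0.429,
                     mental_health: 0.071, sleep: 0.10}
    annual_euro:
      control:      {painkiller: 5, nsaid: 25, dmard: 445,
                     corticosteroid: 22, biologic: 8160,
                     mental_health: 14, sleep: 11}
      intervention: {painkiller: 7, nsaid: 23, dmard: 450,
                     corticosteroid: 23, biologic: 10370,
                     mental_health: 10, sleep: 18}
  productivity:
    presenteeism_prob: 0.4            # per employed patient per quarter
    presenteeism_hours_mean: {control: 74.3, intervention: 92.4}
    presenteeism_sdlog: 1.0
    absence_prob_quarter: {control: 0.0611, intervention: 0.1286}
    absence_duration_mean_weeks: {control: 3.5, intervention: 6.0}
    absence_duration_max_weeks: 16
  treatment_weeks: {mean: 26.07, sd: 12.22, min: 9, max: 65}
  weekly_contact_fraction: 0.5    # weekly vs biweekly therapist contact
  minutes_per_contact: 13.5
  postacademic_fraction: 0.333    # therapists with postacademic training
  two_intake_fraction: 0.5        # second face-to-face intake session
  intake_round_trip_km: 28
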