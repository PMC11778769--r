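# Base-case parameter set for the smoking-cessation decision-tree model.
# A hypothetical cohort of 100,000 smokers (>= 15 years) attending primary
# health care, stratified by Fagerstrom index (FI) score. Monetary values
# in INR; bounds are the published lower/upper values used for sensitivity
# analysis (95% interval convention). Raw FI prevalences sum to 0.98 and
# are normalized at load time.
cohort_size: 100000
wtp_threshold: 235730        # one-time GDP per capita, INR per quitter
wtp_alternative: 216590      # alternative published GDP-per-capita figure
exchange_rate: 83.93         # INR per USD
seed: 20250101

parameters:
  mean_age:      {base: 18.2,  lower: 13.65,   upper: 22.75,   dist: normal}
  prev_fi_0_2:   {base: 0.02,  lower: 0.015,   upper: 0.025,   dist: beta}
  prev_fi_3_5:   {base: 0.11,  lower: 0.083,   upper: 0.138,   dist: beta}
  prev_fi_6_7:   {base: 0.62,  lower: 0.465,   upper: 0.775,   dist: beta}
  prev_fi_8p:    {base: 0.23,  lower: 0.173,   upper: 0.288,   dist: beta}
  quit_bi:       {base: 0.52,  lower: 0.39,    upper: 0.65,    dist: beta}
  quit_nrt2:     {base: 0.6,   lower: 0.45,    upper: 0.75,    dist: beta}
  quit_nrt4:     {base: 0.6,   lower: 0.45,    upper: 0.75,    dist: beta}
  quit_bup:      {base: 0.5,   lower: 0.375,   upper: 0.625,   dist: beta}
  quit_bupsr:    {base: 0.67,  lower: 0.503,   upper: 0.838,   dist: beta}
  quit_ec:       {base: 0.83,  lower: 0.623,   upper: 1,       dist: beta}
  cost_doctor:   {base: 150,   lower: 112.5,   upper: 187.5,   dist: gamma}
  cost_chw:      {base: 76,    lower: 57,      upper: 95,      dist: gamma}
  cost_iec:      {base: 196,   lower: 147,     upper: 245,     dist: gamma}
  cost_nrt2:     {base: 3024,  lower: 2268,    upper: 3780,    dist: gamma}
  cost_nrt4:     {base: 3528,  lower: 2646,    upper: 4410,    dist: gamma}
  cost_bup:      {base: 840,   lower: 630,     upper: 1050,    dist: gamma}
  cost_bupsr:    {base: 1444,  lower: 1082.81, upper: 1804.69, dist: gamma}

strata:
  - {label: "FI 0-2", prevalence: prev_fi_0_2}
  - {label: "FI 3-5", prevalence: prev_fi_3_5}
  - {label: "FI 6-7", prevalence: prev_fi_6_7}
  - {label: "FI >=8", prevalence: prev_fi_8p}

# EC is a motivational package layered on brief advice: its quit effect is
# the independence combination of the EC and BI singleton rates.
components:
  - {name: "BI",           kind: counselling,     quit: [quit_bi],          cost: [cost_doctor, cost_chw]}
  - {name: "EC",           kind: counselling,     quit: [quit_ec, quit_bi], cost: [cost_doctor, cost_chw, cost_iec]}
  - {name: "NRT 2mg",      kind: pharmacotherapy, quit: [quit_nrt2],        cost: [cost_nrt2]}
  - {name: "NRT 4mg",      kind: pharmacotherapy, quit: [quit_nrt4],        cost: [cost_nrt4]}
  - {name: "Bupropion",    kind: pharmacotherapy, quit: [quit_bup],         cost: [cost_bup]}
  - {name: "Bupropion SR", kind: pharmacotherapy, quit: [quit_bupsr],       cost: [cost_bupsr]}

# NRT dosage rises with the FI score; bupropion (plain or SR, by strategy)
# is added only for the high-dependence stratum.
strategies:
  - name: "CS"
    stages:
      "FI 0-2": ["BI"]
      "FI 3-5": ["BI", "NRT 2mg"]
      "FI 6-7": ["BI", "NRT 4mg"]
      "FI >=8": ["BI", "NRT 4mg", "Bupropion"]
  - name: "PS1"
    stages:
      "FI 0-2": ["EC"]
      "FI 3-5": ["EC", "NRT 2mg"]
      "FI 6-7": ["EC", "NRT 4mg"]
      "FI >=8": ["EC", "NRT 4mg", "Bupropion"]
  - name: "PS2"
    stages:
      "FI 0-2": ["BI"]
      "FI 3-5": ["BI", "NRT 2mg"]
      "FI 6-7": ["BI", "NRT 4mg"]
      "FI >=8": ["BI", "NRT 4mg", "Bupropion SR"]
  - name: "PS3"
    stages:
      "FI 0-2": ["EC"]
      "FI 3-5": ["EC", "NRT 2mg"]
      "FI 6-7": ["EC", "NRT 4mg"]
      "FI >=8": ["EC", "NRT 4mg", "Bupropion SR"]

# Published combined quit rates, retained only to validate the
# independence combination rule (the PSA resamples singleton rates).
combined_effects:
  - {name: "EC+BI",           of: [quit_ec, quit_bi],              base: 0.918}
  - {name: "NRT 2mg + BI",    of: [quit_nrt2, quit_bi],            base: 0.808}
  - {name: "NRT 4mg + BI",    of: [quit_nrt4, quit_bi],            base: 0.808}
  - {name: "NRT 2mg + EC+BI", of: [quit_nrt2, quit_ec, quit_bi],   base: 0.967}
  - {name: "NRT 4mg + EC+BI", of: [quit_nrt4, quit_ec, quit_bi],   base: 0.967}
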