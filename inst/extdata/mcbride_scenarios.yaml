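# The eight bundled bias-analysis scenarios for the trichlorophenol-worker
# cohort. Scenarios 1-4: all-cause deaths among the 338 losses follow a
# truncated NegBin(0.02, 3) peaked near 104 (30.9% of 338); scenarios 5-8:
# NegBin(0.027, 2) peaked near 37 (11.0% of 338). Odd scenarios are
# Differential A (never-exposed likeliest fraction 3/4), even are
# Differential B (1/4). The cause-specific proportion is 0.204 (non-Maori
# males) or 0.139 (Maori females); the highest-exposure fraction is 1/2
# and its allocation is capped at the 112 living non-cases of that stratum.
scenarios:
  "1":
    allcause: {prob: 0.02, size: 3, lower: 0, upper: 338}
    cause_proportion: 0.204
    direction: A
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "2":
    allcause: {prob: 0.02, size: 3, lower: 0, upper: 338}
    cause_proportion: 0.204
    direction: B
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "3":
    allcause: {prob: 0.02, size: 3, lower: 0, upper: 338}
    cause_proportion: 0.139
    direction: A
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "4":
    allcause: {prob: 0.02, size: 3, lower: 0, upper: 338}
    cause_proportion: 0.139
    direction: B
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "5":
    allcause: {prob: 0.027, size: 2, lower: 0, upper: 338}
    cause_proportion: 0.204
    direction: A
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "6":
    allcause: {prob: 0.027, size: 2, lower: 0, upper: 338}
    cause_proportion: 0.204
    direction: B
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "7":
    allcause: {prob: 0.027, size: 2, lower: 0, upper: 338}
    cause_proportion: 0.139
    direction: A
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
  "8":
    allcause: {prob: 0.027, size: 2, lower: 0, upper: 338}
    cause_proportion: 0.139
    direction: B
    high_fraction: 0.5
    high_cap: 112
    n_trials: 50000
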