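# MCS score table v1
[mean_loose]
thresholds: 1, 3, 5
points: 0, 1, 2, 3
[mean_nocturnal]
thresholds: 0.5, 1.5, 3.0
points: 0, 1, 2, 3
[urgency_days]
thresholds: 2, 4, 6
points: 0, 1, 2, 3
[leakage_days]
thresholds: 1, 3, 5
points: 0, 1, 2, 3
[mean_pain]
thresholds: 0.5, 1.5, 2.5
points: 0, 1, 2, 3
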