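=== Spirometric transition analysis report ===
criterion: fixed_ratio | tolerance: 0.50 y | any-time: unit | seed: 2026
input md5: d4c37ef901cd982bd603f8ccdf9dd2e1 | package: 0.1.0
counts: subjects_in=200 subjects_analyzed=200 subjects_dropped=0 unclassifiable_sessions=0 duplicate_sessions=0 gaps_outside_window=0 n_units=607

--- Baseline characteristics by state ---
variable         type         normal         gold1          unclassified   gold2plus      p
n                count        122            21             20             37             -
age              continuous   56.3 ± 7.4    57.4 ± 7.7    56.1 ± 8.1    54.3 ± 8.3    0.4621
bmi              continuous   27.9 ± 5.4    29.0 ± 4.8    27.8 ± 7.1    28.4 ± 5.1    0.8115
pack_years       continuous   37.2 ± 11.2   38.1 ± 13.2   37.0 ± 15.4   43.0 ± 13.3   0.08667
fev1_pct_pred    continuous   100.4 ± 10.4  92.0 ± 7.6    68.6 ± 5.3    57.4 ± 12.9   3.427e-58
ratio            continuous   0.787 ± 0.045 0.641 ± 0.035 0.774 ± 0.041 0.543 ± 0.098 2.927e-58
sgrq_total       continuous   18.2 ± 12.1   18.5 ± 12.6   23.2 ± 16.2   33.2 ± 15.8   1.682e-07
male             categorical  18.9%          14.3%          15.0%          18.9%          0.9797
hispanic         categorical  14.8%          14.3%          40.0%          21.6%          0.06704
current_smoker   categorical  58.2%          57.1%          55.0%          40.5%          0.3029
hypertension     categorical  33.6%          38.1%          30.0%          32.4%          0.9546
asthma           categorical  27.9%          33.3%          15.0%          24.3%          0.5583
reversible       categorical  3.3%           0.0%           0.0%           2.7%           1
bhr              categorical  0.8%           0.0%           0.0%           0.0%           1

--- Transition-probability matrix ---
normal       [n=   351] 0.9174 0.0399 0.0427 0.0000
gold1        [n=    69] 0.1449 0.7536 0.0000 0.1014
unclassified [n=    73] 0.0548 0.0000 0.8356 0.1096
gold2plus    [n=   114] 0.0088 0.0175 0.0439 0.9298

--- Beneficial / resolution probabilities ---
group: all
  normal       n=   351  P(beneficial)=0.9174  P(resolution)=NA
  gold1        n=    69  P(beneficial)=0.1449  P(resolution)=0.1449
  unclassified n=    73  P(beneficial)=0.0548  P(resolution)=0.0548
  gold2plus    n=   114  P(beneficial)=0.0702  P(resolution)=0.0088
group: normal_at_baseline
  normal       n=   347  P(beneficial)=0.9251  P(resolution)=NA
  gold1        n=    12  P(beneficial)=0.6667  P(resolution)=0.6667
  unclassified n=    16  P(beneficial)=0.1250  P(resolution)=0.1250
  gold2plus    n=     0  P(beneficial)=NA  P(resolution)=NA
group: abnormal_at_baseline
  normal       n=     4  P(beneficial)=0.2500  P(resolution)=NA
  gold1        n=    57  P(beneficial)=0.0351  P(resolution)=0.0351
  unclassified n=    57  P(beneficial)=0.0351  P(resolution)=0.0351
  gold2plus    n=   114  P(beneficial)=0.0702  P(resolution)=0.0088
group difference (beneficial): logOR=-4.8421 rSE=0.4192 p=7.42e-31
group difference (resolution): logOR=-3.2099 rSE=0.7187 p=7.946e-06

--- Predictor odds ratios ---
model: univariate (n_units=607, n_subjects=200)
  abnormal_start             OR  0.008 ( 0.004,  0.019) p=1.272e-32
  age_ge_60                  OR  1.105 ( 0.653,  1.872) p=0.7098
  male                       OR  1.327 ( 0.656,  2.687) p=0.431
  hispanic                   OR  0.734 ( 0.347,  1.553) p=0.4186
  bmi_ge_25                  OR  0.910 ( 0.472,  1.755) p=0.7794
  hypertension               OR  1.222 ( 0.660,  2.265) p=0.5234
  asthma_plus_reversibility  OR 1633669.601 (224099.764, 11909322.545) p=3.058e-45 [separation?]
model: multivariable (n_units=607, n_subjects=200)
  abnormal_start             OR  0.008 ( 0.004,  0.018) p=1.555e-31
  age_ge_60                  OR  0.841 ( 0.517,  1.366) p=0.4835
  male                       OR  0.954 ( 0.506,  1.796) p=0.8834
  hispanic                   OR  1.241 ( 0.631,  2.441) p=0.5323
  bmi_ge_25                  OR  1.140 ( 0.645,  2.016) p=0.6516
  hypertension               OR  1.624 ( 0.973,  2.710) p=0.06361
  asthma_plus_reversibility  OR 631665.954 (78208.997, 5101738.839) p=5.035e-36 [separation?]
time-varying smoking: OR 1.082 (0.669, 1.749) p=0.7474
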