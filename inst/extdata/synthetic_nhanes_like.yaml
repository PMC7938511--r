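'n': 2000.0
corr:
- - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
  - 1.0e-05
  - 3.0e-06
  - 1.0e-06
  - 0.0e+00
  - 0.0e+00
- - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
  - 1.0e-05
  - 3.0e-06
  - 1.0e-06
  - 0.0e+00
- - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
  - 1.0e-05
  - 3.0e-06
  - 1.0e-06
- - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
  - 1.0e-05
  - 3.0e-06
- - 0.015006
  - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
  - 1.0e-05
- - 0.005252
  - 0.015006
  - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
  - 2.8e-05
- - 0.001838
  - 0.005252
  - 0.015006
  - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
  - 7.9e-05
- - 0.000643
  - 0.001838
  - 0.005252
  - 0.015006
  - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
  - 0.000225
- - 0.000225
  - 0.000643
  - 0.001838
  - 0.005252
  - 0.015006
  - 0.042875
  - 0.1225
  - 0.35
  - 1.0
  - 0.35
  - 0.1225
  - 0.042875
  - 0.015006
  - 0.005252
  - 0.001838
  - 0.000643
- - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
  - 1.225e-01
  - 4.2875e-02
  - 1.5006e-02
  - 5.252e-03
  - 1.838e-03
- - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
  - 1.225e-01
  - 4.2875e-02
  - 1.5006e-02
  - 5.252e-03
- - 1.0e-05
  - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
  - 1.225e-01
  - 4.2875e-02
  - 1.5006e-02
- - 3.0e-06
  - 1.0e-05
  - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
  - 1.225e-01
  - 4.2875e-02
- - 1.0e-06
  - 3.0e-06
  - 1.0e-05
  - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
  - 1.225e-01
- - 0.0
  - 1.0e-06
  - 3.0e-06
  - 1.0e-05
  - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
  - 3.5e-01
- - 0.0
  - 0.0
  - 1.0e-06
  - 3.0e-06
  - 1.0e-05
  - 2.8e-05
  - 7.9e-05
  - 2.25e-04
  - 6.43e-04
  - 1.838e-03
  - 5.252e-03
  - 1.5006e-02
  - 4.2875e-02
  - 1.225e-01
  - 3.5e-01
  - 1.0e+00
var_defs:
- name: exposure
  kind: continuous
  role: exposure
  error_free: no
- name: age
  kind: continuous
  role: baseline_adjustment
  error_free: yes
- name: sex
  kind: binary
  role: baseline_adjustment
  error_free: yes
  thresholds: 0.0
- name: race_ethnicity
  kind: ordinal
  role: adjustment
  error_free: yes
  thresholds:
  - -0.6
  - 0.6
- name: bmi
  kind: continuous
  role: adjustment
  error_free: no
- name: sbp
  kind: continuous
  role: adjustment
  error_free: no
- name: hdl_chol
  kind: continuous
  role: adjustment
  error_free: no
- name: crp
  kind: continuous
  role: adjustment
  error_free: no
- name: thigh_circ
  kind: continuous
  role: adjustment
  error_free: no
- name: glucose
  kind: continuous
  role: adjustment
  error_free: no
- name: smoker
  kind: binary
  role: adjustment
  error_free: no
  thresholds: 0.0
- name: diabetes
  kind: binary
  role: adjustment
  error_free: no
  thresholds: 0.0
- name: heart_disease
  kind: binary
  role: adjustment
  error_free: no
  thresholds: 0.0
- name: alcohol_use
  kind: binary
  role: adjustment
  error_free: no
  thresholds: 0.0
- name: education
  kind: ordinal
  role: adjustment
  error_free: no
  thresholds:
  - -1.2
  - -0.4
  - 0.4
  - 1.2
- name: physical_activity
  kind: ordinal
  role: adjustment
  error_free: no
  thresholds:
  - -0.6
  - 0.6
log_hazards:
- 0.262
- 0.6
- 0.3
- 0.05
- 0.1
- 0.15
- -0.12
- 0.1
- -0.08
- 0.12
- 0.25
- 0.3
- 0.28
- -0.05
- -0.1
- -0.15
baseline_rate: 0.05
censor_rate: 0.15
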