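# Default tissue library (1.5 T). T1/T2 in ms, T2b in microseconds,
# k_exch in 1/s, M0 in arbitrary units. The two-pool MT parameters
# (f_bound, T2b, k_exch) are literature-informed defaults: myocardium and
# liver carry a substantial bound macromolecular pool and are strongly
# MT-attenuated, blood only weakly, fat and lung minimally. class_id is the
# integer label used in the digital phantom (0 = air outside the body).
tissues:
  air:
    class_id: 0
    T1: 100.0
    T2: 20.0
    M0: 0.0
    f_bound: 0.0
    T2b: 10.0
    k_exch: 0.0
    is_fat: false
  lung:
    class_id: 1
    T1: 1200.0
    T2: 30.0
    M0: 0.05
    f_bound: 0.01
    T2b: 9.0
    k_exch: 30.0
    is_fat: false
  arterial_blood:
    class_id: 2
    T1: 1550.0
    T2: 240.0
    M0: 1.0
    f_bound: 0.02
    T2b: 25.0
    k_exch: 25.0
    is_fat: false
    inflow: true
  venous_blood:
    class_id: 3
    T1: 1550.0
    T2: 45.0
    M0: 1.0
    f_bound: 0.02
    T2b: 25.0
    k_exch: 25.0
    is_fat: false
    inflow: true
  myocardium:
    class_id: 4
    T1: 1000.0
    T2: 45.0
    M0: 0.80
    f_bound: 0.20
    T2b: 14.0
    k_exch: 70.0
    is_fat: false
  fat:
    class_id: 5
    T1: 260.0
    T2: 60.0
    M0: 0.90
    f_bound: 0.01
    T2b: 9.0
    k_exch: 30.0
    is_fat: true
  liver:
    class_id: 6
    T1: 580.0
    T2: 45.0
    M0: 0.70
    f_bound: 0.10
    T2b: 8.0
    k_exch: 50.0
    is_fat: false
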