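date,period,mean_nh3,thi
2019-12-22,06:00,50.00,61.45
2019-12-22,12:00,29.40,58.48
2019-12-22,18:00,23.55,58.10
2019-12-23,06:00,25.23,52.59
2019-12-23,12:00,26.98,57.33
2019-12-23,18:00,31.26,57.03
2019-12-24,06:00,33.47,56.34
2019-12-24,12:00,21.75,55.04
2019-12-24,18:00,21.93,54.98
2019-12-25,06:00,44.92,60.97
2019-12-25,12:00,35.63,58.91
2019-12-25,18:00,44.07,61.02
2019-12-26,06:00,38.44,57.33
2019-12-26,12:00,30.46,54.99
2019-12-26,18:00,46.62,55.97
2019-12-29,06:00,24.36,55.48
2019-12-29,12:00,22.55,59.32
2019-12-29,18:00,32.15,57.88
2020-01-02,06:00,19.88,53.13
2020-01-02,12:00,15.60,54.48
2020-01-02,18:00,26.81,56.43
2020-01-03,06:00,23.34,55.95
2020-01-03,12:00,9.14,51.25
2020-01-03,18:00,26.55,56.84
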