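patient,ctv_high_initial_cc,ctv_high_final_cc,ctv_mid_initial_cc,ctv_mid_final_cc,ctv_low_initial_cc,ctv_low_final_cc,rx_ctv_high,rx_ctv_mid,rx_ctv_low,n_fractions,replan_times
1,60.36,61.87,145.59,144.37,404.53,405.59,68.4,64.8,54,36,1
2,84.40,78.73,122.69,115.39,219.41,189.75,70,63,56,35,2
3,68.82,58.46,132.89,136.69,180.18,160.75,70,60.2,53.9,35,1
4,57.67,59.04,84.46,81.94,270.44,243.47,70,63,56,35,1
5,107.90,98.06,–,–,240.13,223.78,70,–,53.9,35,1
6,10.24,9.90,207.09,200.16,263.44,260.07,66,60.06,54.12,33,1
7,96.62,82.96,140.47,114.67,471.0,444.78,70,60.2,53.9,35,1
8,304.31,247.87,–,–,–,–,60,–,–,30,2
9,26.15,25.61,–,–,263.38,222.79,70,–,53.9,35,2
10,235.21,204.53,–,–,516.64,443.40,60,–,54,30,2
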