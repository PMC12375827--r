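country,arm,cost,incremental_cost,effectiveness,incremental_qaly,icer
china,experimental,91983.16,74621.78,0.98,0.14,542441.16
china,control,17361.38,NA,0.84,NA,NA
japan,experimental,78916.38,44014.83,1.00,0.14,314213.67
japan,control,34901.55,NA,0.86,NA,NA
us,experimental,217340.46,160169.86,1.02,0.14,1104628.40
us,control,57170.60,NA,0.88,NA,NA
switzerland,experimental,248359.72,163631.09,1.09,0.15,1069496.82
switzerland,control,84728.63,NA,0.94,NA,NA
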