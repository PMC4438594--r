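parameter,units,group,L4_mean,L4_sd,L5_mean,L5_sd,L6_mean,L6_sd,total_mean,total_sd
bv_tv,%,sham,34.3,5.4,32.8,7.5,39.0,5.3,35.4,6.5
bv_tv,%,ovx,20.0,3.8,23.3,3.3,26.7,3.1,23.3,4.3
bmd,g/cm^3,sham,0.207,0.035,0.251,0.069,0.304,0.075,0.254,0.072
bmd,g/cm^3,ovx,0.066,0.024,0.157,0.062,0.239,0.060,0.154,0.088
tb_th,mm,sham,0.104,0.006,0.104,0.010,0.114,0.006,0.108,0.009
tb_th,mm,ovx,0.106,0.004,0.109,0.004,0.114,0.004,0.110,0.005
tb_sp,mm,sham,0.242,0.015,0.251,0.019,0.264,0.025,0.252,0.022
tb_sp,mm,ovx,0.410,0.078,0.384,0.063,0.367,0.047,0.387,0.064
fd,,sham,2.40,0.05,2.38,0.10,2.43,0.04,2.40,0.07
fd,,ovx,2.23,0.05,2.27,0.03,2.31,0.03,2.27,0.05
tb_pf,1/mm,sham,-1.53,2.84,-0.54,4.85,-3.54,2.57,-1.87,3.67
tb_pf,1/mm,ovx,5.46,1.81,4.02,1.16,2.60,1.34,4.03,1.85
da,,sham,0.806,0.099,0.777,0.103,0.585,0.135,0.723,0.148
da,,ovx,0.901,0.061,0.815,0.101,0.702,0.088,0.806,0.117
conn_dn,1/mm^3,sham,84.6,15.0,87.1,17.8,69.0,7.3,80.2,15.9
conn_dn,1/mm^3,ovx,38.5,8.3,40.6,5.4,45.4,6.2,41.5,7.1
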