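id,age,bmi,mxi_cm,mxp_cm,mdp_cm,ahi_pre,ahi_post,vpx_a_pre,vpx_a_post,vpx_ap_pre,vpx_ap_post,vpx_lat_pre,vpx_lat_post,lpx_a_pre,lpx_a_post,lpx_ap_pre,lpx_ap_post,lpx_lat_pre,lpx_lat_post
mean,39.5,29.0,0.3,0.5,1.1,45.7,11.3,1.2,2.4,0.6,1.1,1.8,2.5,2.3,3.9,1.3,1.9,2.4,3.1
std,12.4,4.6,0.0,0.2,0.1,25.2,11.6,0.9,1.3,0.2,0.3,0.6,0.6,1.0,1.4,0.3,0.5,0.7,0.8
min,25.0,24.5,0.3,0.3,0.9,12.5,0.5,0.4,1.3,0.3,0.8,1.1,1.7,0.6,0.9,1.0,0.9,1.0,1.3
max,55.0,38.6,0.3,0.7,1.3,88.2,36.6,3.1,5.2,1.1,1.8,2.8,3.5,4.0,5.5,1.8,2.5,3.6,3.9
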