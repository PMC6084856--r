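id,dmin_mean,vpx_a_post,vpx_a_sim,vpx_ap_post,vpx_ap_sim,vpx_lat_post,vpx_lat_sim,lpx_a_post,lpx_a_sim,lpx_ap_post,lpx_ap_sim,lpx_lat_post,lpx_lat_sim
mean,0.83,2.4,1.9,1.1,1.1,2.5,1.8,3.9,3.3,1.9,1.9,3.1,2.5
std,0.75,1.3,1.0,0.3,0.3,0.6,0.6,1.4,1.3,0.5,0.5,0.8,0.8
min,0.30,1.3,0.8,0.8,0.7,1.7,1.1,0.9,0.7,0.9,0.9,1.3,1.0
max,2.10,5.2,4.1,1.8,1.6,3.5,2.8,5.5,5.0,2.5,2.5,3.9,3.5
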