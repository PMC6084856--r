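id,dmin_mean,dmin_std,vpx_a_post,vpx_a_sim,vpx_ap_post,vpx_ap_sim,vpx_lat_post,vpx_lat_sim,lpx_a_post,lpx_a_sim,lpx_ap_post,lpx_ap_sim,lpx_lat_post,lpx_lat_sim
1,0.4,0.3,1.9,1.9,1.0,1.2,2.1,1.9,4.9,4.3,2.5,2.4,3.2,2.4
2,0.3,0.3,2.9,2.5,1.1,1.1,3.1,2.5,4.3,2.6,1.9,1.6,3.1,2.6
3,1.8,1.6,1.3,1.3,0.8,1.1,2.4,1.4,4.5,4.0,1.7,1.9,3.7,3.3
4,0.5,0.6,1.6,0.9,0.9,0.9,1.9,1.2,4.2,3.7,2.3,2.5,3.2,3.1
5,1.8,1.4,5.2,4.1,1.8,1.6,3.5,2.8,3.1,2.4,1.8,1.9,2.8,2.0
6,0.3,0.4,1.5,1.4,0.9,0.9,2.0,1.5,2.9,2.2,1.6,1.5,2.7,2.2
7,2.1,1.7,2.9,2.1,1.2,1.2,2.8,2.0,4.1,3.5,2.4,2.2,3.2,1.9
8,0.4,0.5,1.3,0.8,0.9,0.8,1.7,1.1,1.9,2.2,1.4,1.2,1.7,1.5
9,0.3,0.4,3.6,2.9,1.4,1.2,3.3,2.4,5.5,5.0,1.8,1.7,3.9,3.5
10,0.4,0.3,1.7,1.1,0.8,0.7,2.4,1.6,0.9,0.7,0.9,0.9,1.3,1.0
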