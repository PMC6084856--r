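id,age,sex,bmi,mxi_cm,mxp_cm,mdp_cm,ahi_pre,ahi_post,vpx_a_pre,vpx_a_post,vpx_ap_pre,vpx_ap_post,vpx_lat_pre,vpx_lat_post,lpx_a_pre,lpx_a_post,lpx_ap_pre,lpx_ap_post,lpx_lat_pre,lpx_lat_post
1,37,M,27.6,0.3,0.3,1.2,34.3,4.7,0.9,1.9,0.6,1.0,1.9,2.1,3.4,4.9,1.8,2.5,2.5,3.2
2,25,F,25.7,0.3,0.3,1.0,20.0,0.5,1.7,2.9,0.7,1.1,2.5,3.1,1.6,4.3,1.2,1.9,2.6,3.1
3,53,M,38.6,0.3,0.6,1.3,59.1,2.8,0.4,1.3,0.3,0.8,1.4,2.4,3.1,4.5,1.3,1.7,3.2,3.7
4,37,M,28.9,0.3,0.5,1.0,43.1,14.6,0.4,1.6,0.4,0.9,1.2,1.9,1.9,4.2,1.3,2.3,2.1,3.2
4,37,M,28.9,0.3,0.5,1.0,43.1,14.6,0.4,1.6,0.4,0.9,1.2,1.9,1.9,4.2,1.3,2.3,2.1,3.2
5,25,F,24.5,0.3,0.7,1.0,12.5,7.0,3.1,5.2,1.1,1.8,2.8,3.5,2.7,3.1,1.7,1.8,2.5,2.8
6,30,F,25.1,0.3,0.6,1.1,30.8,4.8,0.8,1.5,0.5,0.9,1.5,2.0,2.0,2.9,1.4,1.6,2.3,2.7
7,49,M,33.2,0.3,0.3,1.2,27.8,10.8,1.2,2.9,0.7,1.2,2.0,2.8,1.9,4.1,1.3,2.4,2.1,3.2
8,55,F,32.5,0.3,0.5,0.9,65.2,5.1,0.5,1.3,0.5,0.9,1.1,1.7,1.6,1.9,1.0,1.4,1.6,1.7
9,29,F,24.7,0.3,0.6,0.9,88.2,36.6,2.1,3.6,0.8,1.4,2.4,3.3,4.0,5.5,1.3,1.8,3.6,3.9
10,55,F,29.4,0.3,0.3,1.1,76.0,26.5,0.5,1.7,0.3,0.8,1.6,2.4,0.6,0.9,1.0,0.9,1.0,1.3
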