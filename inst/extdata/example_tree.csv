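segment_id,parent_id,artery,length_cm,mean_radius_cm,has_stenosis,is_measurement_site,site_distance_cm
LAD_prox,,LAD,3.5,0.2,false,false,
LAD_sten,LAD_prox,LAD,1.5,0.06,true,false,
LAD_site,LAD_sten,LAD,1.2,0.19,false,true,6.2
LAD_d1,LAD_site,LAD,6,0.15,false,false,
LCX_prox,,LCX,3,0.17,false,false,
LCX_sten,LCX_prox,LCX,1.8,0.07,true,false,
LCX_site,LCX_sten,LCX,1.4,0.165,false,true,6.2
RCA_prox,,RCA,4,0.21,false,false,
RCA_d1,RCA_prox,RCA,7,0.16,false,false,
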