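record_id,province,year,season,treatment,root_fresh_yield_t_ha,leaf_fresh_yield_t_ha,root_dm_t_ha,leaf_dm_t_ha,root_n_g_kg,root_p_g_kg,root_k_g_kg,leaf_n_g_kg,leaf_p_g_kg,leaf_k_g_kg
D001,Hebei,2015,autumn,OPT,72.4,28.1,3.91,2.05,27.5,6.1,45.2,33.0,5.0,30.8
D002,Hebei,2015,autumn,CK,41.2,18.9,2.43,1.41,24.1,5.2,40.6,29.4,4.4,27.5
D003,Hebei,2015,autumn,minusN,55.8,20.3,3.07,1.52,19.8,6.4,47.0,24.6,5.3,32.1
D004,Shandong,2016,autumn,OPT,88.0,30.5,4.66,2.20,29.3,6.6,48.8,34.2,5.5,31.9
D005,Shandong,2016,autumn,minusP,63.5,24.0,3.37,1.75,28.2,4.3,46.1,32.7,3.4,30.2
D006,Shandong,2016,autumn,minusK,59.1,23.2,3.19,1.69,28.9,6.3,36.4,33.5,5.2,24.0
D007,Tianjin,2016,spring,OPT,76.9,26.8,4.15,1.98,26.8,6.0,44.0,31.8,4.9,29.6
D008,Tianjin,2016,spring,FP,68.3,25.5,3.62,1.87,30.1,6.9,51.3,35.0,5.7,33.4
D009,Zhejiang,2017,autumn,OPT,81.6,29.7,4.32,2.08,27.1,6.2,45.9,32.4,5.1,30.4
D010,Zhejiang,2017,autumn,CK,35.4,16.1,2.12,1.23,23.3,4.9,38.7,28.1,4.1,26.3
D011,Beijing,2017,spring,OPT,66.7,,3.57,,28.4,6.3,46.5,,,
D012,Beijing,2017,spring,minusN,49.9,19.5,2.79,1.48,18.9,6.1,45.1,23.8,5.0,31.0
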