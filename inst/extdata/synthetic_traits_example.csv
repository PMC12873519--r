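species,leaf_length_cm,d_pet_um,d_twig_um,wood_density_g_cm3,height_m,leaf_type,site
sp001,36.0881,23.9671,26.8628,0.148299,12.5674,compound,site_3
sp002,11.0499,36.405,67.414,0.229502,3.18246,compound,site_1
sp003,9.13276,17.9154,20.8725,0.140716,3.90897,simple,site_3
sp004,27.5456,34.9769,49.8202,0.357694,3.5926,simple,site_3
sp005,17.1526,47.9071,46.9247,0.196298,16.2156,simple,site_3
sp006,1.90551,11.9673,15.887,0.463623,3.70616,simple,site_1
sp007,22.6226,26.4531,38.496,0.334211,30.4946,simple,site_2
sp008,11.3515,15.2008,17.8073,0.340157,0.49527,compound,site_2
sp009,59.7797,32.1408,50.5639,0.20375,7.85254,compound,site_1
sp010,12.426,21.7058,39.2528,0.148809,5.25431,simple,site_1
sp011,10.2637,18.1699,37.2161,0.256648,2.56354,compound,site_2
sp012,65.0196,49.0159,76.1614,0.277554,40.6866,compound,site_3
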