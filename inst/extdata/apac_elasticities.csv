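group_id,gni_lower,gni_upper,constant,constant_se,beta_price,beta_price_se,beta_gni,beta_gni_se,beta_fctc,beta_fctc_se,hausman,r_squared,weak_id_F,n_obs,n_countries
1,0,999,1.435,0.203,-0.037,0.068,-0.161,0.076,0.02,0.012,60.07,0.256,91.131,68,4
2,1000,1999,0.919,0.182,-0.146,0.089,0.046,0.061,-0.048,0.005,7.41,0.533,146.45,102,6
3,2000,2999,-0.072,0.256,-0.488,0.289,0.408,0.078,-0.154,0.027,34.56,0.919,23.555,68,4
4,3000,3999,0.831,0.564,-0.267,0.238,0.017,0.165,-0.072,0.023,34.65,0.849,23.663,51,3
5,4000,5999,0.269,0.341,-0.614,0.155,0.327,0.098,-0.045,0.023,39.08,0.657,79.333,51,3
6,6000,,-0.757,0.552,-1.304,0.306,0.769,0.161,-0.103,0.046,20.81,0.387,21.077,34,2
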