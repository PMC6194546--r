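country,income_group,excise_type,specific_share,advalorem_share,prevalence,consumption_2015,price_2015
Cambodia,1,ad_valorem,0,0.1315,0.18,22.47,1.34
Nepal,1,specific,0.1629,0,0.271,27.0,1.09
Bangladesh,1,ad_valorem,0,0.61,0.223,23.02,0.5
Myanmar,1,ad_valorem,0,0.50,0.238,7.86,0.12
India,2,mixed,0.4225,0.012,0.134,23.9,1.62
Laos,2,mixed,0.0625,0.014,0.353,27.38,0.68
Vietnam,2,ad_valorem,0,0.325,0.186,47.97,0.58
Bhutan,2,none,,,0.288,5.52,1.18
Papua New Guinea,2,specific,0.2642,0,0.267,25.37,0.99
Solomon Islands,2,specific,0.1915,0,0.1928,0.64,3.67
Indonesia,3,mixed,0.4091,0.0409,0.31,50.52,1.34
Mongolia,3,specific,0.3326,0,0.243,36.65,0.78
Sri Lanka,3,mixed,0.5915,0.0391,0.128,11.84,2.07
Vanuatu,3,specific,0.4444,0,0.26,1.71,3.53
Philippines,4,specific,0.6355,0,0.201,42.12,1.18
Samoa,4,specific,0.4232,0,0.373,1.21,3.53
Tonga,4,specific,0.5882,0,0.359,1.83,3.27
Fiji,5,specific,0.3105,0,0.109,19.8,2.61
Maldives,5,none,0,0,0.24,7.57,1.16
Thailand,5,mixed,0.0286,0.6372,0.161,35.92,1.83
China,6,mixed,0.006,0.293,0.305,95.94,2.59
Malaysia,6,mixed,0.4167,0.0893,0.23,21.14,2.97
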