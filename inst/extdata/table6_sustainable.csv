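class,floodplain forests,Amazon forests,fragmented forests and secondary vegetation,grasslands and shrublands,pastures and crops,urban and artificialized cover,water bodies and wetlands
floodplain forests,0.95,0.00,0.03,0.00,0.01,0.00,0.00
Amazon forests,0.00,0.97,0.00,0.00,0.02,0.00,0.00
fragmented forests and secondary vegetation,0.07,0.17,0.73,0.00,0.01,0.00,0.00
grasslands and shrublands,0.00,0.00,0.02,0.96,0.01,0.00,0.00
pastures and crops,0.00,0.00,0.27,0.01,0.71,0.00,0.00
urban and artificialized cover,0.00,0.00,0.02,0.04,0.03,0.90,0.00
water bodies and wetlands,0.00,0.00,0.00,0.00,0.08,0.00,0.90
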