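class,floodplain forests,Amazon forests,fragmented forests and secondary vegetation,grasslands and shrublands,pastures and crops,urban and artificialized cover,water bodies and wetlands,suspect
floodplain forests,0.87,0.00,0.01,0.00,0.10,0.00,0.00,FALSE
Amazon forests,0.00,0.88,0.02,0.00,0.08,0.00,0.00,FALSE
fragmented forests and secondary vegetation,0.01,0.06,0.15,0.84,0.12,0.00,0.00,TRUE
grasslands and shrublands,0.00,0.00,0.02,0.84,0.12,0.00,0.00,TRUE
pastures and crops,0.00,0.00,0.09,0.01,0.88,0.01,0.00,FALSE
urban and artificialized cover,0.00,0.00,0.00,0.00,0.07,0.92,0.00,FALSE
water bodies and wetlands,0.00,0.00,0.00,0.00,0.08,0.00,0.90,FALSE
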