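class,reference_2016_ha,reference_2016_pct,bau_2040_ha,bau_2040_pct,extractivist_2040_ha,extractivist_2040_pct,sustainable_2040_ha,sustainable_2040_pct
floodplain forests,4288790,8.9,4142512,8.5,3780879,7.8,4210149,8.7
Amazon forests,35673007,73.9,33779460,70.0,31826314,65.7,35123495,72.8
fragmented forests and secondary vegetation,1824387,3.8,2223369,4.6,1773849,3.6,2681416,5.5
grasslands and shrublands,1895873,3.9,1678145,3.5,1653770,3.4,1882283,3.9
pastures and crops,3970030,8.2,5878568,12.2,8617274,17.8,3804739,7.8
urban and artificialized cover,13380,0.1,13380,0.1,13380,0.1,13380,0.1
water bodies and wetlands,581340,1.2,531372,1.1,581340,1.2,531344,1.1
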