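submodel,from,to,area_ha
degradation,floodplain forests,grasslands and shrublands,8909
degradation,floodplain forests,fragmented forests and secondary vegetation,48740
degradation,Amazon forests,grasslands and shrublands,8935
degradation,Amazon forests,fragmented forests and secondary vegetation,664181
substitution,grasslands and shrublands,pastures and crops,164121
substitution,water bodies and wetlands,pastures and crops,33356
substitution,floodplain forests,pastures and crops,45562
substitution,fragmented forests and secondary vegetation,pastures and crops,681206
substitution,Amazon forests,pastures and crops,923154
regeneration,grasslands and shrublands,fragmented forests and secondary vegetation,23678
regeneration,pastures and crops,grasslands and shrublands,15927
regeneration,pastures and crops,fragmented forests and secondary vegetation,385628
regeneration,fragmented forests and secondary vegetation,floodplain forests,13706
regeneration,fragmented forests and secondary vegetation,Amazon forests,75832
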