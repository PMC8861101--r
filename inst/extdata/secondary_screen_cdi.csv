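mimic_id,v_mimic,v_combo,cdi
hsa-miR-145-3p,0.75,0.15,0.27
hsa-miR-676-3p,0.66,0.16,0.32
hsa-miR-1181,0.90,0.33,0.50
hsa-miR-376b-5p,0.54,0.20,0.51
hsa-miR-18b-5p,1.11,0.44,0.54
hsa-miR-3187-3p,0.57,0.25,0.59
hsa-miR-548v,0.41,0.19,0.64
hsa-miR-718,0.91,0.43,0.64
hsa-miR-3687,1.07,0.51,0.65
hsa-miR-99a-3p,0.92,0.46,0.67
hsa-miR-655-5p,0.56,0.28,0.68
hsa-miR-449c-5p,0.38,0.19,0.70
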