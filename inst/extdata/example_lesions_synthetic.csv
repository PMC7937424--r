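subject_id,lesion_type,hu_unenhanced,hu_enhanced,hu_delayed,size_mm
L01,carcinoma,34.0,74.8,62.6,85
L02,adenoma,33.0,89.3,71.2,55
L03,incidentaloma,-5.0,2.75,-2.16,26
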