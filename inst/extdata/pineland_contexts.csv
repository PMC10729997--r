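context_id,site_area,period_label,strat_order
Old Mound 1 (A-8-101),old_mound,Caloosahatchee I,NA
Surf Clam Ridge (Trench 11B-93),surf_clam_ridge,Caloosahatchee I,NA
Low Mound (A-1-77-1),low_mound,Caloosahatchee I,NA
Old Mound 2 (A-16-92),old_mound,Caloosahatchee IIA,NA
Brown's Complex 1 (C-6-92-1),browns_complex,Caloosahatchee IIA,NA
Brown's Complex 2 (C-5-88-2),browns_complex,Caloosahatchee IIA,NA
Brown's Complex 3 (C-5-79-1),browns_complex,Caloosahatchee IIA,NA
Randell Complex 1 (A-Prof-63),randell_complex,Caloosahatchee IIB,NA
Randell Complex 2 (A-Prof-55),randell_complex,Caloosahatchee IIB,NA
Brown's Complex Mound 2a (I-2-73),browns_mound_2,Caloosahatchee III,NA
Brown's Complex Mound 2b (I-2-66),browns_mound_2,Caloosahatchee IV,NA
Operation P (P-10-99),operation_p,Operation P level 99,4
Operation P (P-10-101),operation_p,Operation P level 101,3
Operation P (P-1-103),operation_p,Operation P level 103,2
Operation P (P-10-105),operation_p,Operation P level 105,1
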