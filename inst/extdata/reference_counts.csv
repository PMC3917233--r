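genotype,timepoint_dag,median_cell_count,median_total_area_um2
Col-0,15,883,70000
Col-0,35,18124,2000000
Ler,15,260,11000
Ler,35,11026,1000000
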