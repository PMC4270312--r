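{"seed":1,"n_compounds":24,"n_replicates":4,"active_compounds":[1,2,3,4,5,6,7,8],"active_scaling":0.7,"genotype_factor":1.5,"base_amplitude":0.8,"n_cells":60,"noise_cv":0.02,"cell_cv":0.2,"fraction_nonresponsive":0.1,"responder_theta":0.1,"hit_threshold":0.9,"down_threshold":0.8,"up_threshold":1.25,"min_responsive_frac":0.2,"render":false,"schedule":{"timestamps":[0,2.5,5,6,7,8,9,10,12.5,15,17.5,20,22.5],"dispense_index":4}}
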