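intention,system_action,correct,n_sequences,sequence_duration_ms,keyboard_size,is_correction
skip,skip,,3,4500,69,FALSE
skip,skip,,3,4500,69,FALSE
selection,selection,FALSE,2,4500,69,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,FALSE,3,4500,63,FALSE
selection,selection,TRUE,2,3750,55,FALSE
selection,selection,FALSE,3,4500,63,FALSE
selection,skip,,3,4500,69,FALSE
skip,selection,,1,4500,63,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,skip,,3,4500,69,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,selection,FALSE,2,3750,49,FALSE
selection,selection,TRUE,2,4500,63,FALSE
skip,selection,,2,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,3750,55,FALSE
selection,selection,TRUE,1,3750,55,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,skip,,3,4500,69,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,FALSE,3,4500,69,FALSE
selection,selection,TRUE,1,3750,55,FALSE
selection,skip,,3,4500,63,FALSE
selection,skip,,3,4500,69,FALSE
skip,skip,,3,4500,69,FALSE
selection,skip,,3,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,skip,,3,4500,63,FALSE
selection,skip,,3,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,skip,,3,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,FALSE,3,4500,63,FALSE
selection,selection,FALSE,3,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
skip,skip,,3,4500,63,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,63,FALSE
skip,skip,,3,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,FALSE,3,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,3750,55,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,FALSE,3,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,FALSE,2,4500,63,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,selection,FALSE,3,4500,69,FALSE
selection,skip,,3,4500,69,FALSE
selection,selection,FALSE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,FALSE,3,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,skip,,3,3750,49,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,FALSE,2,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
skip,skip,,3,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
skip,skip,,3,4500,63,FALSE
skip,skip,,3,4500,63,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,FALSE,2,3750,49,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,skip,,3,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,selection,TRUE,1,3750,55,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,FALSE,3,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,selection,FALSE,2,4500,69,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,3750,49,FALSE
selection,skip,,3,4500,63,FALSE
selection,selection,TRUE,1,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,TRUE,2,4500,63,FALSE
selection,selection,TRUE,1,4500,69,FALSE
selection,selection,FALSE,2,3750,55,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,TRUE,2,4500,69,FALSE
selection,selection,FALSE,2,4500,69,FALSE
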