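"marker","metal_tag","stain_class","all33","stim20","annotation9","annotation9_stim","cytokines"
"CD3","In115","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD11a","La139","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD11b","Pr141","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD11c","Nd142","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD14","Nd143","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD16","Nd144","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD19","Nd145","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD23","Nd146","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD28","Sm147","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD32","Nd148","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD64","Sm149","extracellular",TRUE,TRUE,FALSE,TRUE,FALSE
"CD66","Nd150","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CD86","Eu151","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CD123","Sm152","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"CCR5","Eu153","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"CXCR4","Sm154","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"GranzymeB","Gd155","intracellular",TRUE,TRUE,TRUE,FALSE,FALSE
"Perforin","Gd156","intracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"TLR2","Gd158","extracellular",TRUE,TRUE,FALSE,FALSE,FALSE
"HLADR","Tb159","extracellular",TRUE,TRUE,TRUE,TRUE,FALSE
"MIP1b","Gd160","intracellular",TRUE,FALSE,FALSE,FALSE,TRUE
"TNFa","Dy161","intracellular",TRUE,FALSE,FALSE,FALSE,TRUE
"IL8","Dy162","intracellular",TRUE,FALSE,FALSE,FALSE,TRUE
"CD45","Dy163","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD15","Dy164","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD20","Ho165","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD24","Er166","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD36","Er167","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD38","Er168","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD56","Tm169","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD62L","Er170","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"CD69","Yb171","extracellular",TRUE,FALSE,FALSE,FALSE,FALSE
"IL6","Yb172","intracellular",TRUE,FALSE,FALSE,FALSE,FALSE
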