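site,vegetation,habitat,latitude,richness,NRI,NTI
Amazonian 1,Amazon forest,forest,3°6'S,61,-1.821,0.607
Amazonian 2,Amazon forest,forest,11°31'S,45,-1.431,1.413
Atlantic 1,Atlantic forest,forest,14°47'S,55,-0.054,1.709
Atlantic 2,Atlantic forest,forest,24°32'S,28,0.359,1.030
Atlantic 3,Atlantic forest,forest,25°47'S,20,1.220,-0.592
Atlantic 4,Atlantic forest,forest,28°14'S,13,0.931,0.932
Cerrado 1,Cerrado savanna,non_forest,8°50'S,24,-0.488,-0.130
Cerrado 2,Cerrado savanna,non_forest,10°22'S,27,-0.794,0.275
Cerrado 3,Cerrado savanna,non_forest,15°48'S,42,0.941,0.253
Cerrado 4,Cerrado savanna,non_forest,22°15'S,29,1.149,-1.173
Campos 1,Campos grassland,non_forest,29°26'S,9,2.743,1.282
Campos 2,Campos grassland,non_forest,29°41'S,18,1.718,0.654
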