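Type,Advantages,Disadvantages
Line,1,2
Bar,1,2
Tree,1,3
ParallelCoordinate,3,2
Nightingale Rose,3,3
Multidimensional Rose,4,2
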