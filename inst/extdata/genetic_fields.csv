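label,priority,vertex,d13c,d2h
thermogenic,1,1,-50,-300
thermogenic,1,2,-20,-300
thermogenic,1,3,-20,-100
thermogenic,1,4,-50,-100
acetoclastic,2,1,-65,-400
acetoclastic,2,2,-50,-400
acetoclastic,2,3,-50,-250
acetoclastic,2,4,-65,-250
hydrogenotrophic,3,1,-110,-250
hydrogenotrophic,3,2,-60,-250
hydrogenotrophic,3,3,-60,-150
hydrogenotrophic,3,4,-110,-150
mixed_methanogenic,4,1,-110,-400
mixed_methanogenic,4,2,-65,-400
mixed_methanogenic,4,3,-65,-250
mixed_methanogenic,4,4,-110,-250
oxidized_or_thermogenic,5,1,-60,-300
oxidized_or_thermogenic,5,2,-50,-300
oxidized_or_thermogenic,5,3,-50,-100
oxidized_or_thermogenic,5,4,-60,-100
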