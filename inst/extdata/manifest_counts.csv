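class,images,boxes,tracks
Ctenophora,20695,28800,203
Aurelia aurita,26542,27330,109
Cyanea capillata,11838,11838,26
Gadus morhua,7725,8141,210
Fish unspecified,3310,6163,215
Clupeidae,1846,5001,335
Jellyfish unspecified,2160,2262,12
Salmonidae,599,1479,23
Scomber scombrus,133,964,53
Pleuronectoidei,921,921,12
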