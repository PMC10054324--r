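class,images_train,images_val,boxes_train,boxes_val
Ctenophora,17412,3283,24297,4503
Aurelia aurita,22486,4056,23131,4199
Cyanea capillata,9414,2424,9414,2424
Gadus morhua,6255,1470,6617,1524
Fish unspecified,2564,746,4864,1299
Clupeidae,1001,845,3588,1413
Jellyfish unspecified,1836,324,1918,344
Salmonidae,452,147,1192,287
Scomber scombrus,116,17,863,101
Pleuronectoidei,774,147,774,147
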