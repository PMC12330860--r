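section,diameter_um,frequency
genu,0.4,420
genu,0.6,520
genu,0.8,330
genu,1.0,140
genu,1.5,40
genu,2.0,8
anterior_body,0.4,300
anterior_body,0.6,470
anterior_body,0.8,360
anterior_body,1.0,220
anterior_body,1.5,90
anterior_body,2.0,30
anterior_body,3.0,6
isthmus,0.4,180
isthmus,0.6,330
isthmus,0.8,340
isthmus,1.0,290
isthmus,1.5,170
isthmus,2.0,90
isthmus,3.0,40
isthmus,4.0,12
splenium,0.4,240
splenium,0.6,420
splenium,0.8,350
splenium,1.0,250
splenium,1.5,120
splenium,2.0,45
splenium,3.0,12
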