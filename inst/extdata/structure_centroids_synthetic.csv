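structure,x,y,z
postcentral gyrus,-42,-25,50
middle frontal gyrus,-38,30,35
posterior cingulate,-5,-45,25
inferior parietal,-45,-50,45
subgenual cingulate,-4,25,-10
superior frontal gyrus,-20,30,50
inferior frontal gyrus,-48,25,15
inferior temporal gyrus,-50,-30,-25
orbitofrontal cortex,-25,40,-15
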