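# kind=viscosity wavelength_nm=610
"condition","intensity"
1.2,107.87
3.111,164.451
8.066,245.486
20.914,374.302
54.223,566.193
140.583,862.999
364.487,1297.015
945,1945.812
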