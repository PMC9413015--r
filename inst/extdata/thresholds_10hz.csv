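measure,rate_hz,sleep_floor,sed_light,light_mod,mod_vig
enmonz,10,0.0001,0.032,0.173,0.382
mad,10,0.001,0.059,0.242,0.38
ai,10,0.010,5.308,17.010,23.628
rocam,10,0.06,0.175,0.400,0.483
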