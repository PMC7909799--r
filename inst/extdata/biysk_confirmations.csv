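site,method,n_events,n_confirmed
zareche,outbreak,7,7
zareche,mwm,7,5
zareche,mica,5,4
sokolovo,outbreak,9,8
sokolovo,mwm,9,9
sokolovo,mica,9,5
lesnoye,outbreak,5,5
lesnoye,mwm,5,3
lesnoye,mica,5,2
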