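site,year
zareche,1949
zareche,1959
zareche,1972
zareche,1978
zareche,1986
zareche,1996
zareche,2001
sokolovo,1915
sokolovo,1924
sokolovo,1930
sokolovo,1941
sokolovo,1949
sokolovo,1972
sokolovo,1984
sokolovo,1995
sokolovo,2002
lesnoye,1949
lesnoye,1959
lesnoye,1978
lesnoye,1990
lesnoye,1995
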