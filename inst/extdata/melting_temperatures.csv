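protein,variant,phospho_state,tm_C
MAPK1,WT,NP,55.0
MAPK1,WT,P,55.0
MAPK1,E81K,NP,55.0
MAPK1,E81K,P,54.1
MAPK1,R135K,NP,55.1
MAPK1,R135K,P,55.1
MAPK1,D162G,NP,49.0
MAPK1,D162G,NP,60.0
MAPK1,D162G,P,60.0
MAPK1,R191H,NP,58.0
MAPK1,R191H,P,58.1
MAPK1,Y316F,NP,55.1
MAPK1,Y316F,P,55.1
MAPK1,P319S,NP,51.0
MAPK1,P319S,P,55.1
MAPK1,E322V,NP,57.1
MAPK1,E322V,P,56.0
MAPK1,E33Q,NP,54.1
MAPK1,E33Q,P,59.0
MAPK1,L121I,NP,55.0
MAPK1,L121I,P,62.0
MAPK1,L200F,NP,54.0
MAPK1,L200F,P,56.1
MAPK1,D235V,NP,52.1
MAPK1,D235V,P,61.1
MAPK3,WT,NP,46.0
MAPK3,WT,P,47.1
MAPK3,E98K,NP,52.0
MAPK3,E98K,P,47.1
MAPK3,R152W,NP,49.0
MAPK3,R152W,P,42.0
MAPK3,R152W,P,58.0
MAPK3,P336Q,NP,44.0
MAPK3,P336Q,P,47.0
MAPK3,E339V,NP,46.1
MAPK3,E339V,P,48.1
MAPK3,I73M,NP,45.0
MAPK3,I73M,P,46.0
MAPK3,I73M,P,58.0
MAPK3,Q79H,NP,44.1
MAPK3,Q79H,NP,59.0
MAPK3,Q79H,P,47.1
MAPK3,A160T,NP,42.1
MAPK3,A160T,P,44.1
MAPK3,T198I,NP,58.0
MAPK3,T198I,NP,75.0
MAPK3,T198I,P,48.0
MAPK3,E214D,NP,48.0
MAPK3,E214D,NP,59.0
MAPK3,E214D,NP,74.0
MAPK3,E214D,P,51.0
MAPK3,E214D,P,61.1
MAPK3,L281I,NP,46.1
MAPK3,L281I,P,47.1
MAPK3,V290A,NP,47.0
MAPK3,V290A,P,56.0
MAPK3,R359W,NP,43.1
MAPK3,R359W,P,56.1
MAPK3,E362K,NP,44.1
MAPK3,E362K,P,46.0
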