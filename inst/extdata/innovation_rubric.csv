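species,market,patent,literature,printed_score
Achillea millefolium,0,1,1,22
Agrimonia eupatoria,0,0,2,22
Berberis aquifolium,1,3,1,56
Betula pendula,1,1,2,44
Borago officinalis,0,1,0,11
Capsella bursa-pastoris,3,3,1,78
Clematis vitalba,2,2,2,67
Cormus domestica,3,2,2,78
Corylus avellana,2,2,2,67
Dipsacus fullonum,2,1,2,56
Lactuca serriola,0,1,3,44
Narcissus jonquilla,3,2,1,67
Plantago lanceolata,0,0,1,11
Plantago major,0,1,0,11
Polygonatum multiflorum,1,1,2,44
Portulaca oleracea,0,0,1,11
Primula veris,2,2,2,67
Spartium junceum,3,3,1,78
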