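species,extract,dpph,hyaluronidase,tyrosinase,lipoxygenase,collagenase,printed_extract_score,printed_species_score,is_reference
Commercial reference,REF,++++,++++,++++,++++,+,80,80,TRUE
Molecular reference,REF,++++,++++,++++,++++,+++,85,85,TRUE
Achillea millefolium,HA,++++,++++,-,-,-,40,38,FALSE
Achillea millefolium,PG,+++,++++,-,-,-,35,38,FALSE
Agrimonia eupatoria,HA,++++,++++,-,+++,-,55,53,FALSE
Agrimonia eupatoria,PG,++++,++++,-,++,-,50,53,FALSE
Berberis aquifolium,HA,++++,n.d.,-,++,-,37.5,41,FALSE
Berberis aquifolium,PG,++++,n.d.,-,+++,-,43.8,41,FALSE
Betula pendula,HA,+++,++++,-,+++,-,50,55,FALSE
Betula pendula,PG,++++,++++,-,++++,-,60,55,FALSE
Borago officinalis,HA,++,++,-,+,-,25,30,FALSE
Borago officinalis,PG,++,++++,-,+,-,35,30,FALSE
Capsella bursa-pastoris,HA,-,n.d.,-,++,-,12.5,22,FALSE
Capsella bursa-pastoris,PG,+,n.d.,-,++++,-,31.3,22,FALSE
Clematis vitalba,HA,++++,++++,-,+++,-,55,60,FALSE
Clematis vitalba,PG,++++,++++,+,+++,+,65,60,FALSE
Cormus domestica,HA,++++,n.d.,++,+,n.d.,58.3,54,FALSE
Cormus domestica,PG,++,n.d.,++,++,n.d.,50,54,FALSE
Corylus avellana,HA,+++,++++,-,++++,-,60,60,FALSE
Corylus avellana,PG,++++,++++,-,++++,-,60,60,FALSE
Dipsacus fullonum,HA,++,++++,-,++,n.d.,50,50,FALSE
Lactuca serriola,HA,++++,+++,n.d.,+,n.d.,66.7,54,FALSE
Lactuca serriola,PG,++,+++,n.d.,-,n.d.,41.7,54,FALSE
Narcissus jonquilla,HA,+,+,-,+,n.d.,18.8,12,FALSE
Narcissus jonquilla,PG,-,+,-,-,n.d.,5,12,FALSE
Plantago lanceolata,HA,+,++++,-,-,-,25,30,FALSE
Plantago lanceolata,PG,+,++++,-,-,++,35,30,FALSE
Plantago major,HA,++++,++++,-,+,-,45,43,FALSE
Plantago major,PG,++++,++++,-,-,-,40,43,FALSE
Polygonatum multiflorum,HA,-,n.d.,+,-,n.d.,8.3,4,FALSE
Polygonatum multiflorum,PG,-,n.d.,-,-,n.d.,0,4,FALSE
Portulaca oleracea,HA,-,+,-,-,-,5,13,FALSE
Portulaca oleracea,PG,-,++++,-,-,-,20,13,FALSE
Primula veris,HA,+,++++,-,++,-,35,40,FALSE
Primula veris,PG,+++,++++,-,++,-,45,40,FALSE
Spartium junceum,HA,+,+,n.d.,-,n.d.,16.7,25,FALSE
Spartium junceum,PG,++,++,n.d.,-,n.d.,33.3,25,FALSE
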