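locality,age,tree_taxon,tree_group,resin_class,mass_min_g,mass_max_g,approximate,total_inclusions,citation
"Mananjary region (between Nosy Varika and Ambahy), Madagascar","Resin collected in 2013","Hymenaea verrucosa",hymenaea,defaunation,800.5,800.5,FALSE,1743,"Solorzano-Kraemer et al. 2015"
"Sacaramy (close to Antsiranana, Diego Suarez), Madagascar","Resin collected in 2015","Hymenaea verrucosa",hymenaea,defaunation,1500,1500,FALSE,2141,"Own data"
"Col de Yate South Province (Gramseat South), New Caledonia","Resin collected in 2016","Agathis ovata",agathis,defaunation,1627.1,1627.1,FALSE,40,"Own data"
"Bon Secours (close to Riviere Bleue Provincial Park, South Province, Gramseat South), New Caledonia","Resin collected in 2016","Agathis lanceolata",agathis,defaunation,991.6,991.6,FALSE,8,"Own data"
"Cotui, Dominican Republic","Unknown","Hymenaea courbaril",hymenaea,copal,1875.2,1875.2,FALSE,319,"Own data"
"Totolapa, Chiapas, Mexico","Early Miocene","Hymenaea mexicana",hymenaea,amber,2000,2000,FALSE,107,"Solorzano-Kraemer et al. 2007"
"El Valle 7 Canadas, Dominican Republic","Early Miocene","Hymenaea protera",hymenaea,amber,1678.8,1678.8,FALSE,270,"Own data"
"San Rafael, Dominican Republic","Early Miocene","Hymenaea protera",hymenaea,amber,523.5,523.5,FALSE,140,"Own data"
"Southland region of the South Island, and Otago, New Zealand","Late Oligocene and early Miocene","Agathis sp.",agathis,amber,1000,1500,TRUE,78,"Schmidt et al. 2018"
"Anglesea Coal Measures (ACM), Australia","Early Eocene","Agathis sp.",agathis,amber,2000,2000,TRUE,47,"Stilwell et al. 2020; own data 2025"
"Macquarie Harbour Formation (MHF), Australia","Early Eocene","Agathis sp.",agathis,amber,1500,1500,TRUE,2,"Stilwell et al. 2020; own data 2025"
"Fourtou, France","Middle Cenomanian","Agathoxylon sp. or Cheirolepidiaceae",cheirolepidiaceae,amber,2000,2000,TRUE,40,"Girard et al.; own data 2025"
"Fouras/Bois Vert, France","Early Cenomanian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,3000,3000,TRUE,113,"Neraudeau et al.; Perrichot et al.; own data 2025"
"Ile d'Aix, France","Early Cenomanian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,500,500,TRUE,6,"Neraudeau et al.; own data 2025"
"La Buzinie, France","Early Cenomanian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,6000,6000,TRUE,149,"Perrichot et al.; own data 2025"
"Salignac, France","Early Cenomanian","Araucariaceae",agathis_like,amber,400,400,TRUE,27,"Perrichot et al.; own data 2025"
"Archingeay-Les Nouillers, France","Late Albian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,35000,40000,FALSE,1330,"Perrichot et al.; own data 2025"
"Les Renardieres, France","Late Albian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,300,300,FALSE,4,"Perrichot et al.; own data 2025"
"Cadeuil, France","Late Albian","Agathoxylon gardoniense and Cheirolepidiaceae",cheirolepidiaceae,amber,8000,8000,TRUE,98,"Neraudeau et al.; own data 2025"
"Penacerrada, Alava, Spain","Late Albian (Early Cretaceous)","Agathis-like",agathis_like,amber,139500,139500,FALSE,3346,"Own data"
"San Just, Teruel, Spain","Late Albian (Early Cretaceous)","Agathis-like",agathis_like,amber,12900,12900,FALSE,387,"Own data"
"La Hoya, Castellon, Spain","Early Cenomanian (Early Cretaceous)","Agathis-like",agathis_like,amber,5500,5500,FALSE,11,"Own data"
"El Soplao, Cantabria, Spain","Middle Albian (Early Cretaceous)","Frenelopsis sp. (Cheirolepidiaceae) and other possible Cupressaceae",cheirolepidiaceae,amber,19937,19937,FALSE,1600,"Own data"
"Arroyo de la Pascueta, Teruel, Spain","Late Albian (Early Cretaceous)","Agathis-like",agathis_like,amber,7000,7000,FALSE,14,"Own data"
"La Rodada, La Manjoya, Spain","Late Albian (Early Cretaceous)","Agathis-like",agathis_like,amber,500,500,FALSE,2,"Penalver et al."
"Arino, Teruel, Spain","Early Albian (Early Cretaceous)","Agathis-like",agathis_like,amber,1128,1128,FALSE,100,"Own data"
"Doumanga, Congo","Middle Aptian","Agathoxylon sp. or Cheirolepidiaceae",cheirolepidiaceae,amber,2550,2550,FALSE,47,"Bouju and Perrichot; own data 2025"
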