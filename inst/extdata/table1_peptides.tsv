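sequence	amidated	frequency	name	group	insect	artefact
CYIQNCPLG	TRUE	0	oxytocin	mammals	FALSE	FALSE
CYFQNCPRG	TRUE	0	vasopressin	mammals	FALSE	FALSE
CYIQNCPRG	TRUE	0	vasotocin	non-mammalian vertebrates	FALSE	FALSE
CLITNCPRG	TRUE	57	inotocin	insects	TRUE	FALSE
CFITNCPPG	TRUE	32	inotocin-like	arthropods	FALSE	FALSE
CLITNCPKG	TRUE	8	inotocin-like	insects	TRUE	FALSE
CFITNCPIG	TRUE	3		Symphylella vulgaris; Metaseiulus occidentalis; Varroa destructor	FALSE	FALSE
CLIINCPRG	TRUE	2		Athalia rosae; Neodiprion lecontei	TRUE	FALSE
CLITNCPIG	TRUE	2		Haploembia palaui; Leptinotarsa decemlineata	TRUE	FALSE
CFISNCPVS	TRUE	2		Calanus finmarchicus	FALSE	FALSE
CMIINCPRG	TRUE	2		Gryllotalpa sp.; Teleogryllus commodus	TRUE	FALSE
CFITNCPRA	TRUE	1		Dermatophagoides farinae	FALSE	FALSE
CFITNCPPA	TRUE	1		Sarcoptes scabiei	FALSE	FALSE
CFITNCPSG	TRUE	1		Tigriopus californicus	FALSE	FALSE
CLIVNCPRG	TRUE	1		Camponotus floridanus	TRUE	FALSE
CLITNCPHG	TRUE	1		Dinoponera quadriceps	TRUE	FALSE
CYITNCPWG	TRUE	1		Arachnocampa luminosa	TRUE	TRUE
CLISNCPKG	TRUE	1		Pachypsylla venusta	TRUE	FALSE
CLINNCPTG	TRUE	1		Diaphorina citri	TRUE	FALSE
CYITNCPPG	TRUE	1		Strigamia maritima	FALSE	FALSE
CFILDCPLM	FALSE	1		Speleonectes cf. tulumensis	FALSE	FALSE
CYIINCIDND	TRUE	1		Scolopendra subspinipes	FALSE	FALSE
CFITNCPVGG	TRUE	1		Lepeophtheirus salmonis	FALSE	FALSE
CFITNCPVGS	TRUE	1		Caligus rogercresseyi	FALSE	FALSE
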