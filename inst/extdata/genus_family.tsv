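genus	family
Acetobacter	Acetobacteraceae
Acidicaldus	Acetobacteraceae
Acidiphilium	Acetobacteraceae
Acidisphaera	Acetobacteraceae
Acidocella	Acetobacteraceae
Acidomonas	Acetobacteraceae
Ameyamaea	Acetobacteraceae
Asaia	Acetobacteraceae
Belnapia	Acetobacteraceae
Bombella	Acetobacteraceae
Commensalibacter	Acetobacteraceae
Endobacter	Acetobacteraceae
Gluconacetobacter	Acetobacteraceae
Gluconobacter	Acetobacteraceae
Granulibacter	Acetobacteraceae
Komagataeibacter	Acetobacteraceae
Kozakia	Acetobacteraceae
Neoasaia	Acetobacteraceae
Neokomagataea	Acetobacteraceae
Nguyenibacter	Acetobacteraceae
Oleomonas	Acetobacteraceae
Paracraurococcus	Acetobacteraceae
Rhodopila	Acetobacteraceae
Rhodovarius	Acetobacteraceae
Roseococcus	Acetobacteraceae
Roseomonas	Acetobacteraceae
Saccharibacter	Acetobacteraceae
Stella	Acetobacteraceae
Swaminathania	Acetobacteraceae
Swingsia	Acetobacteraceae
Tanticharoenia	Acetobacteraceae
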