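# Starter privileged-substructure library (synthetic stand-in).
# These are common privileged cores from the medicinal-chemistry literature,
# shipped so the pipeline runs out of the box; replace with your own curated
# pattern set for production analyses.
# Format: NAME<TAB>PATTERN (SMILES or SMARTS), one per line.
indole	c1ccc2c(c1)cc[nH]2
benzimidazole	c1ccc2c(c1)nc[nH]2
quinoline	c1ccc2ncccc2c1
isoquinoline	c1ccc2cnccc2c1
biphenyl	c1ccc(-c2ccccc2)cc1
diphenylmethane	C(c1ccccc1)c1ccccc1
benzofuran	c1ccc2c(c1)cco2
benzothiophene	c1ccc2c(c1)ccs2
carbazole	c1ccc2c(c1)[nH]c1ccccc12
purine	c1ncc2[nH]cnc2n1
arylpiperazine	c1ccc(N2CCNCC2)cc1
arylpiperidine	c1ccc(C2CCNCC2)cc1
chromone	O=c1ccoc2ccccc12
quinazoline	c1ccc2ncncc2c1
indazole	c1ccc2[nH]ncc2c1
benzodiazepine	O=C1CN=C(c2ccccc2)c2ccccc2N1
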