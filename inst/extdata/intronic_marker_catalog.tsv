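allele	hgvs_c	location
ABO*B.01	c.28+4282A>G	Intron 1
ABO*B.01	c.28+6120T>C	Intron 1
ABO*B.01	c.29-4732T>G	Intron 1
ABO*B.01	c.29-4604G>A	Intron 1
ABO*B.01	c.29-3924C>T	Intron 1
ABO*B.01	c.29-86G>A	Intron 1
ABO*B.01	c.240-25A>G	Intron 5
ABO*B.01	c.374+42G>T	Intron 6
ABO*B.01	c.374+271A>G	Intron 6
ABO*B.01	c.374+280C>T	Intron 6
ABO*B.01	c.375-425A>G	Intron 6
ABO*B.01	c.375-152G>A	Intron 6
ABO*O.01.01	c.29-780delinsGG	Intron 1
ABO*O.01.01	c.29-746T>C	Intron 1
ABO*O.01.01	c.29-658G>A	Intron 1
ABO*O.01.01	c.98+362C>T	Intron 1
ABO*O.01.01	c.99-186C>A	Intron 1
ABO*O.01.01	c.155+575C>T	Intron 3
ABO*O.01.01	c.204-9T>C	Intron 4
ABO*O.01.01	c.240-219G>A	Intron 5
ABO*O.01.01	c.374+163C>T	Intron 6
ABO*O.01.01	c.375-269G>A	Intron 6
ABO*O.01.02	c.28+175C>T	Intron 1
ABO*O.01.02	c.29-554A>C	Intron 1
ABO*O.01.02	c.29-286A>C	Intron 1
ABO*O.01.02	c.155+205C>T	Intron 3
ABO*O.01.02	c.155+479C>T	Intron 3
ABO*O.01.02	c.155+525A>T	Intron 3
ABO*O.01.02	c.156-483T>C	Intron 3
ABO*O.01.02	c.156-389A>G	Intron 3
ABO*O.01.02	c.156-208C>T	Intron 3
ABO*O.01.02	c.156-174T>C	Intron 3
ABO*O.01.02	c.156-95C>T	Intron 3
ABO*O.01.02	c.203+28G>C	Intron 4
ABO*O.01.02	c.203+72_203+73insGTGTGGACAGAAG	Intron 4
ABO*O.01.02	c.203+114C>T	Intron 4
ABO*O.01.02	c.203+163G>A	Intron 4
ABO*O.01.02	c.203+215_203+216delinsGC	Intron 4
ABO*O.01.02	c.203+346T>G	Intron 4
ABO*O.01.02	c.203+738T>G	Intron 4
ABO*O.01.02	c.204-511C>T	Intron 4
ABO*O.01.02	c.204-220G>A	Intron 4
ABO*O.01.02	c.204-191T>C	Intron 4
ABO*O.01.02	c.204-176T>G	Intron 4
ABO*O.01.02	c.204-61dupC	Intron 4
ABO*O.01.02	c.239+103_239+105insC[3]	Intron 5
ABO*O.01.02	c.240-249C>T	Intron 5
ABO*O.01.02	c.240-105C>A	Intron 5
ABO*O.01.02	c.240-28G>A	Intron 5
ABO*O.01.02	c.374+89T>A	Intron 6
ABO*O.01.02	c.374+188G>A	Intron 6
ABO*O.01.02	c.374+226C>T	Intron 6
ABO*O.01.02	c.374+235C>G	Intron 6
ABO*O.01.02	c.374+493T>C	Intron 6
ABO*O.01.02	c.375-336G>A	Intron 6
ABO*O.01.02	c.375-42A>G	Intron 6
ABO*O.01.02	c.375-40G>A	Intron 6
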