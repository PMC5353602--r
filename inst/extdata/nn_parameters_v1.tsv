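step	dh_kcal_mol	ds_cal_k_mol	source
AA/TT	-7.9	-22.2	SantaLucia-2004-unified-WC
AT/TA	-7.2	-20.4	SantaLucia-2004-unified-WC
CA/GT	-8.5	-22.7	SantaLucia-2004-unified-WC
CG/GC	-10.6	-27.2	SantaLucia-2004-unified-WC
CT/GA	-7.8	-21.0	SantaLucia-2004-unified-WC
GA/CT	-8.2	-22.2	SantaLucia-2004-unified-WC
GC/CG	-9.8	-24.4	SantaLucia-2004-unified-WC
GG/CC	-8.0	-19.9	SantaLucia-2004-unified-WC
GT/CA	-8.4	-22.4	SantaLucia-2004-unified-WC
TA/AT	-7.2	-21.3	SantaLucia-2004-unified-WC
init_AT	2.3	4.1	SantaLucia-2004-unified-WC
init_GC	0.1	-2.8	SantaLucia-2004-unified-WC
sym	0	-1.4	SantaLucia-2004-unified-WC
AA/TA	1.2	1.7	Peyret-1999-identical
AA/TC	2.3	4.6	Allawi-SantaLucia-1998-AC
AA/TG	-0.6	-2.3	Allawi-SantaLucia-1998-GA
AC/TA	5.3	14.6	Allawi-SantaLucia-1998-AC
AC/TC	0.0	-4.4	Peyret-1999-identical
AC/TT	0.7	0.2	Allawi-SantaLucia-1998-CT
AG/TA	-0.7	-2.3	Allawi-SantaLucia-1998-GA
AG/TG	-3.1	-9.5	Peyret-1999-identical
AG/TT	1.0	0.9	Allawi-SantaLucia-1997-GT
AT/TC	-1.2	-6.2	Allawi-SantaLucia-1998-CT
AT/TG	-2.5	-8.3	Allawi-SantaLucia-1997-GT
AT/TT	-2.7	-10.8	Peyret-1999-identical
CA/GA	-0.9	-4.2	Peyret-1999-identical
CA/GC	1.9	3.7	Allawi-SantaLucia-1998-AC
CA/GG	-0.7	-2.3	Allawi-SantaLucia-1998-GA
CC/GA	0.6	-0.6	Allawi-SantaLucia-1998-AC
CC/GC	-1.5	-7.2	Peyret-1999-identical
CC/GT	-0.8	-4.5	Allawi-SantaLucia-1998-CT
CG/GA	-4.0	-13.2	Allawi-SantaLucia-1998-GA
CG/GG	-4.9	-15.3	Peyret-1999-identical
CG/GT	-4.1	-11.7	Allawi-SantaLucia-1997-GT
CT/GC	-1.5	-6.1	Allawi-SantaLucia-1998-CT
CT/GG	-2.8	-8.0	Allawi-SantaLucia-1997-GT
CT/GT	-5.0	-15.8	Peyret-1999-identical
GA/CA	-2.9	-9.8	Peyret-1999-identical
GA/CC	5.2	14.2	Allawi-SantaLucia-1998-AC
GA/CG	-0.6	-1.0	Allawi-SantaLucia-1998-GA
GC/CA	-0.7	-3.8	Allawi-SantaLucia-1998-AC
GC/CC	3.6	8.9	Peyret-1999-identical
GC/CT	2.3	5.4	Allawi-SantaLucia-1998-CT
GG/CA	0.5	3.2	Allawi-SantaLucia-1998-GA
GG/CG	-6.0	-15.8	Peyret-1999-identical
GG/CT	3.3	10.4	Allawi-SantaLucia-1997-GT
GG/TT	5.8	16.3	Allawi-SantaLucia-1997-GT-tandem
GT/CC	5.2	13.5	Allawi-SantaLucia-1998-CT
GT/CG	-4.4	-12.3	Allawi-SantaLucia-1997-GT
GT/CT	-2.2	-8.4	Peyret-1999-identical
GT/TG	4.1	9.5	Allawi-SantaLucia-1997-GT-tandem
TA/AA	4.7	12.9	Peyret-1999-identical
TA/AC	3.4	8.0	Allawi-SantaLucia-1998-AC
TA/AG	0.7	0.7	Allawi-SantaLucia-1998-GA
TC/AA	7.6	20.2	Allawi-SantaLucia-1998-AC
TC/AC	6.1	16.4	Peyret-1999-identical
TC/AT	1.2	0.7	Allawi-SantaLucia-1998-CT
TG/AA	3.0	7.4	Allawi-SantaLucia-1998-GA
TG/AG	1.6	3.6	Peyret-1999-identical
TG/AT	-0.1	-1.7	Allawi-SantaLucia-1997-GT
TG/GT	-1.4	-6.2	Allawi-SantaLucia-1997-GT-tandem
TT/AC	1.0	0.7	Allawi-SantaLucia-1998-CT
TT/AG	-1.3	-5.3	Allawi-SantaLucia-1997-GT
TT/AT	0.2	-1.5	Peyret-1999-identical
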