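# Curated differentially expressed long ncRNAs in developing forelimb,
# transcribed from the published tabulation (orientation is the printed
# label relative to the closest coding gene; codes: +1 up, -1 down, 0 none).
symbol	ucsc_id	location	conservation_mean	orientation	closest_coding_gene	de_E13.5_vs_E11.5	de_E15.5_vs_E13.5
AK019125	uc007byu.1	Chr1	0.08663	head-to-head	Arl4c	1	-1
AK003315 (Myeov2)	uc007cbq.1	Chr1	0.05824	head-to-tail	Otos	-1	0
AK014513	uc007eem.1	Chr1	0.10996	tail-to-head	Camk1g	1	1
AK082757	uc008iue.1	Chr2	0.06682	tail-to-head	Btbd14a	0	1
AK007459	uc008iuf.1	Chr2	0.27284	head-to-head	Btbd14a	0	1
C130021l20Rik	uc008jhz.1	Chr2	0.13674	head-to-head	Lmx1b	0	-1
AK030275	uc008ltx.1	Chr2	0.13798	head-to-tail	Sid470	0	-1
BC048556	uc008mgc.1	Chr2	0.21847	tail-to-head	Nphp1	1	1
AK007971	uc008nqb.1	Chr2	0.09166	tail-to-tail	Lbp	0	-1
AK012506	uc008onz.1	Chr3	0.34076	antisense	Zfhx4	0	-1
AK007373	uc008rbp.1	Chr3	0.09312	head-to-head	Dph5	-1	0
BC096391 (Snhg8)	uc008rfm.1	Chr3	0.20019	tail-to-tail	Prss12	0	-1
AK080292	uc008rzc.1	Chr4	0.17915	head-to-head	Ccne2	0	-1
NR_003270 (Snhg3)	uc008vbf.1	Chr4	0.33261	head-to-tail	Phactr4	-1	-1
AK083203	uc008wbz.1	Chr4	0.09120	head-to-head	Prdm16	0	-1
AK012278	uc008xth.1	Chr5	0.22535	head-to-head	Usp46	-1	0
2610001J05Rik	uc009ayt.1	Chr6	0.13108	tail-to-head	Gpr85	1	0
AK002748	uc009bxj.1	Chr6	0.05646	head-to-head	Nfe2l3	1	0
AK033508	uc009byt.1	Chr6	0.19038	head-to-head	Hoxa13	-1	-1
AK039589	uc009cib.1	Chr6	0.08391	head-to-tail	St3gal5	1	-1
AK170805	uc009ejz.1	Chr6	0.11942	head-to-head	Tas2r140	1	0
AK011885	uc009ely.1	Chr6	0.28077	head-to-head	Atf7ip	1	0
H19	uc009kob.1	Chr7	0.25529	tail-to-tail	Mrpl23	-1	1
AK134636	uc009las.1	Chr8	0.13898	tail-to-head	4930467E23Rik	1	0
Phxr4	uc009odu.1	Chr9	0.09209	tail-to-head	Maml2	1	0
BC003348	uc009oek.1	Chr9	0.66034	head-to-tail	Sesn3	0	-1
AK165129	uc007htj.1	Chr11	0.37820	head-to-head	Morc2a	1	-1
AK162965	uc007jdh.1	Chr11	0.18394	head-to-head	Mrp155	1	-1
AK079857	uc007kol.1	Chr11	0.06137	head-to-tail	Slfn3	1	-1
BC037520	uc007mmx.1	Chr11	0.10152	tail-to-head	Sec14l1	1	1
AK164256	uc007msb.1	Chr11	0.19866	head-to-head	Bahcc1	0	-1
1700012B15Rik	uc007mwg.1	Chr12	0.64135	tail-to-tail	Rab10	0	1
AK035058	uc007nvz.1	Chr12	0.30950	tail-to-tail	Six1	0	-1
AF498300 (Rian)	uc007paz.1	Chr12	0.05280	head-to-head	Rtl1	1	1
BC025054	uc007pyi.1	Chr13	0.11581	head-to-tail	Sox4	1	-1
AK087718	uc007pip.1	Chr13	0.15192	tail-to-head	Gdi2	-1	-1
AK021143	uc007qip.1	Chr13	0.06779	head-to-head	Fam120a	1	-1
AK020502	uc007qlx.1	Chr13	0.09589	head-to-head	Spin1	0	-1
AK029385	uc007vaf.1	Chr14	0.20634	tail-to-head	Slc15a1	-1	0
AK011684	uc007vbc.1	Chr14	0.25107	head-to-head	Zic2	-1	0
DQ715667	uc007wbs.1	Chr15	0.44104	tail-to-tail	Chrac1	-1	1
AK085438	uc007wpq.1	Chr15	0.10360	tail-to-head	Rac2	1	-1
AK005956	uc007zwv.1	Chr16	0.13992	head-to-head	1110004E09Rik	-1	1
AK004150	uc008cek.1	Chr17	0.09964	head-to-tail	Hspa1b	0	-1
Malat1	uc008gfj.1	Chr19	0.34059	tail-to-head	Scyl1	1	0
Neat1	uc008gfk.1	Chr19	0.18959	head-to-tail	Frmd8	1	1
AK051045	uc008gmk.1	Chr19	0.23573	head-to-head	Slc3a2	0	-1
AK030946	uc009tdn.1	ChrX	0.04767	head-to-tail	2610018G03Rik	1	-1
AK008724	uc009ura.1	ChrX	0.21428	head-to-head	Kctd12b	1	0
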