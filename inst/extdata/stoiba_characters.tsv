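index	description
0	Head, well exposed=0 (Fig. 81); mostly concealed=1 (Figs 11–40); entirely concealed=2 (Figs 82–83)
1	Antennomeres III–X, mainly pale yellow=0 (Figs 11–40); brown with black or mixed=1 (Figs 84–86)
2	Antennomere III (Figs 47–56), 2 times as long or longer than II=0; less than 2 times=1
3	Antennomere III (Figs 47–56), shorter than IV=0; as long as IV or slightly longer (1.1 times)=1; distinctly longer (over 1.2 times)=2
4	Antennomere VII (Figs 47–56), longer than width=0; broader than length or as broad as long=1
5	Mandible, teeth number five=0 (Fig. 58); 4 or 4 with vestigial teeth=1 (Fig. 59)
6	Mandible, without horizontal thickening=0 (Figs 100–101); with horizontal thickening=1 (Figs 58–59)
7	Labial palpomere I shape, sub-quadrate=0 (Fig. 102); triangular=1 (Figs 62– 63, 103)
8	Pronotum, anterior edge continuous=0 (Figs 82–91); discontinuous=1 (Fig. 81)
9	Prosternum, antero-lateral edge rounded or slightly angled=0 (Fig. 64); distinctly angled=1
10	Pronotum, base, angled=0 (Figs 84–86); transverse=1 (Figs 87–91)
11	Pronotum, widest at base=0 (Figs 82–86, 88); at middle=1 (Figs 87, 99); at front=2 (Fig. 81)
12	Pronotum, basal line, linear=0 (Figs 87–91); sinuate=1 (Figs 85–86); rounded=2 (Figs 81–83)
13	Pronotum postero-medial angle extending more than postero-lateral margin=0; (Figs 82, 84–86); not extended or slightly extended=1 (Figs 83, 87–91)
14	Prosternal process, slightly inflated=0 (Fig. 64); straight sided=1
15	Scutellum, hidden or small=0 (Figs 84, 88–91); well exposed=1 (Figs 81–83, 85–87)
16	Meso-, metanotum, separated=0 (Figs 65–66), fused=1 (Fig. 84)
17	Metasternum, medially broad and flat=0 (Fig. 67); not flat with deep groove medially=1
18	Elytral disc height/length ratio, less than 0.34=0 (Fig. 30); between 0.35-0.5=1 (Fig. 33); over 0.5=2
19	Elytra surface, smooth=0 (Figs 29, 82–87); rough=1 (Figs 11, 32, 81, 88–91)
20	Elytral puncture size, small=0 (Fig. 82–87); large=1 (Figs 81, 88–81)
21	Elytral punctuation, fine=0 (Fig. 29); rough=1 (Fig. 32); coarse (Figs 88–91)
22	Base of elytral disc, distinctly broader than discal base of pronotum=0 (Fig. 84); as broad as or slightly broader=1 (Fig. 85–86); narrower=2 (Figs 87–91)
23	Elytra, umbone indistinct=0 (Figs 87–91); distinct=1 (Figs 81–86)
24	Elytra margin, lateral edge, rounded=0 (Figs 81–87); angled=1 (Figs 88–91)
25	Elytra margin expanded toward vento-laterally=0 (81–86); horizontally=1 (87–91)
26	Elytra margin posterior half distinct from disc=0 (Fig. 23); vague=1 (Fig. 29)
27	Elytral suture, separate=0 (Fig. 35), partly fused=1 (Fig. 89), fused=2 (Fig. 88)
28	Elytral longitudinal carina and brace, parallel=0 (Fig. 96); angled=1 (Fig. 95)
29	Hind wing, fully developed=0 (Fig. 92); brachypterous=1 (Fig. 93); vestigial=2 (Fig. 94)
30	Claw basal tooth absent=0; present=1 (Figs 97–98)
31	Claw basal part, simple=0; quadrate=1 (Fig. 97); pointed=2 (Fig. 98)
32	Spermathecal duct, short=0; long=1(Figs 72–80)
33	Spermathecal receptacle, short=0, shorter than ¼ of pump (Fig. 72); long, over ¼ of pump length =1 (Fig. 73)
34	Spermathecal duct, loosely coiled=0 (Fig. 79); tightly coiled=1 (Fig. 74)
35	Male genitalia, deversment=1; without deversment=0
36	Seminal vesicle, much thicker than ejaculatory duct=0 (Fig. 99); slightly thicker=1 (Figs 68–71)
37	Aedeagal spicule, divided into two segments=0 (Fig. 99); not divided, Y or V-shaped=1 (Figs 68–71)
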