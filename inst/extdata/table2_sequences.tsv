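id	sequence	length	known_energy
1	HPPHHPH	7	-2
2	HPHHHPHHPH	10	-4
3	HPPHPPPPHPPHP	13	-4
4	HHPHPPHPHPHHPH	14	-6
5	HPHHHHHHHHHPHH	14	-7
6	HHHPPHHHHHPHHH	14	-7
7	HHHHHPPHHHHPHH	14	-7
8	HPHHPPPHHHHHHH	14	-6
9	HHHPHHPPPHHPHH	14	-6
10	HHPHHHHHPPPPPH	14	-4
11	HHPPHHHPHPPHPH	14	-6
12	HHHPPPPHPHHPHH	14	-5
13	HPHPPHHPHPPHPHHPPHPH	20	-9
14	HHHPPHPHPHPPHPHPHPPH	20	-10
15	HHHHHPHHPHHHHPPHHHHHH	21	-12
16	PHPPHPHHHPHPPHPHHHPPH	21	-9
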