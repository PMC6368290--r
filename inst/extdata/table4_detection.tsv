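case	jct	chrA	truth_start	chrB	truth_stop	pe_start	pe_stop	mp_start	mp_stop	om_start	om_stop	lr_start	lr_stop	sn_start	sn_stop	estimated
1	1	15	55083064	2	209425831	55083064	209425831	55083064	209425759	55089032	209402341	N.i.	N.i.	55083064	209425831	FALSE
1	2	2	211567929	2	211580954	211567929	211580954	211567929	211580954	N.i.	N.i.	N.i.	N.i.	211567929	211567929	FALSE
1	3	15	55083060	2	211580725	55083060	211580725	55074707	211580771	55065367	211588781	N.i.	N.i.	55083060	211580725	FALSE
1	4	2	212551644	8	129040042	212551644	129040042	212551653	129040144	212542133	129041041	N.i.	N.i.	212551644	129040001	FALSE
1	5	2	214880375	8	114508085	214880375	114508085	214886416	114500483	214907985	114499568	N.i.	N.i.	N.i.	N.i.	FALSE
2	1	1	196997343	5	124956736	196997343	124956736	196994135	124956869	196978354	124976031	196997346	124956731	N.i.	N.i.	FALSE
2	2	1	196997432	10	20816222	196997432	20816222	197000507	20816587	197040164	20824882	196997340	20816229	N.i.	N.i.	FALSE
2	3	10	20816224	5	124956733	20816224	124956733	20812880	124958603	20804445	124913158	20816227	124956736	20816225	124956734	FALSE
2	4	10	4689832	10	19120882	4689832	19120882	4689419	19120882	4669757	19134619	19120884	4689840	N.i.	N.i.	FALSE
3	1	1	2581232	1	27452000	N.i.	N.i.	N.i.	N.i.	2587901	27464776	N.i.	N.i.	2624548	27452144	TRUE
3	2	1	2684269	1	14176001	N.i.	N.i.	N.i.	N.i.	2684269	14173037	N.i.	N.i.	2625721	14175578	TRUE
3	3	1	3290905	1	64810516	3290905	64810516	3290638	64810985	3288732	64862703	N.i.	N.i.	3290905	64810516	FALSE
3	4	1	3296814	1	236176103	3296814	236176103	N.i.	N.i.	N.i.	N.i.	3295874	236176381	3296360	236176372	FALSE
3	5	1	7682335	1	12897986	7682335	12897986	7682260	12898340	7681134	12908586	7682180	12898137	N.i.	N.i.	FALSE
3	6	1	7685352	1	236183504	7685352	236183504	7689171	236183789	7685681	236193515	7685344	236183496	N.i.	N.i.	FALSE
3	7	1	10775956	1	21736058	10775956	21736058	10773838	21736071	10768488	21736601	10775947	14443168	N.i.	N.i.	FALSE
3	8	1	10775956	1	14443177	10775956	14443177	10780413	14443430	N.i.	N.i.	10775964	21736050	N.i.	N.i.	FALSE
3	9	1	11950223	1	27642518	11950223	27642518	11949895	27642567	11947447	28085587	11950233	27642509	N.i.	N.i.	FALSE
3	10	1	11950229	1	237674299	11950229	237674299	11952419	237674508	14864206	237679257	11950220	237674290	11950229	237674299	FALSE
3	11	1	12029894	1	14870594	12029894	14870594	12029206	14869373	N.i.	N.i.	12029904	14870604	12029894	14870594	FALSE
3	12	1	13975090	1	14870595	13975090	14870595	13974941	14871025	13973279	14872976	13975098	14870587	13975090	14870595	FALSE
3	13	1	13975102	1	35045018	13975102	35045018	13977983	35046971	13982091	35047391	13975094	35045018	13975102	35045018	FALSE
3	14	1	16136097	1	23235619	16136097	23235619	16135371	23235980	16129345	23237153	16136105	23235661	16136097	23235619	FALSE
3	15	1	16136098	1	20149345	16136098	20149345	16139274	20149848	N.i.	N.i.	16136089	20149366	16136098	20149345	FALSE
3	16	1	16147000	1	29030516	16147000	29030516	16146491	29025749	N.i.	N.i.	16147010	29030525	N.i.	N.i.	FALSE
3	17	1	16147001	1	23117213	16147001	23117213	16149609	23119367	16153803	23120068	16136105	23235661	16147001	23117213	FALSE
3	18	1	20149331	1	26177921	20149331	26177921	20149195	26174604	20123909	26163960	20149340	26177929	N.i.	N.i.	FALSE
3	19	1	21736058	1	27642518	21736058	27642518	21735951	27639797	21721930	27627697	21736067	27642527	N.i.	N.i.	FALSE
3	20	1	23117213	1	64810516	23117213	64810516	23117169	64806842	23116865	64808492	23117222	64810424	23117213	64810516	FALSE
3	21	1	23235618	1	26177922	23235618	26177922	23235543	26178144	23234405	26178892	23235614	26177914	23235618	26177922	FALSE
3	22	1	27414473	1	29030516	27414473	29030516	27413006	29030699	27400938	29032646	27414484	29030566	N.i.	N.i.	FALSE
3	23	1	27667160	1	28083088	27667160	28083088	27667122	28083292	N.i.	N.i.	27667283	28083081	27667278	28083088	FALSE
3	24	1	27667279	1	246033001	27667279	246033001	27669970	246033207	27673872	246031926	27667271	246033016	27667279	246033001	FALSE
3	25	1	28083088	1	35045017	28083088	35045017	28082851	35042558	28075475	35043873	28083097	35045020	N.i.	N.i.	FALSE
3	26	1	237674294	1	246030822	237674294	246030822	237674208	246027906	237673047	246031926	237674304	246030756	N.i.	N.i.	FALSE
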