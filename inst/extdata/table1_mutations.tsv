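sample_id	group	mutation	predicted_deleterious	abundance	complex_printed	hotspot_printed
B107	BRCA1	G266E	TRUE	NA	0	1
B109	BRCA1	R213X	TRUE	NA	1	1
B109	BRCA1	H214Y	TRUE	NA	1	1
B116	BRCA1	Y163C	TRUE	NA	0	1
B118	BRCA1	NA	NA	NA	NA	NA
B119	BRCA1	NA	NA	NA	NA	NA
B122	BRCA1	239 insT	TRUE	NA	1	0
B124	BRCA1	NA	NA	NA	NA	NA
B125	BRCA1	NA	NA	NA	NA	NA
B126	BRCA1	del 255	TRUE	NA	1	0
B127	BRCA1	T55I	FALSE	NA	0	0
B135	BRCA1	wild type	NA	NA	0	0
B137	BRCA1	224 splice G > A	TRUE	NA	1	0
B141	BRCA1	wild type	NA	NA	0	0
B145	BRCA1	110 delC	TRUE	NA	1	0
B145	BRCA1	Q100X	TRUE	NA	1	0
B146	BRCA1	145 delG	TRUE	NA	1	0
B146	BRCA1	Q104X	TRUE	NA	1	0
B146	BRCA1	P98S	FALSE	NA	1	0
B149	BRCA1	R273H	TRUE	NA	0	1
B150	BRCA1	V216 M	TRUE	NA	0	1
B150	BRCA1	P223 S	FALSE	NA	0	1
B150	BRCA1	R290C	FALSE	NA	0	1
B152	BRCA1	R175H	TRUE	NA	0	1
B153	BRCA1	del 155-156	TRUE	NA	1	0
B156	BRCA1	R248W	TRUE	NA	0	1
B156	BRCA1	R280K	TRUE	NA	0	1
B156	BRCA1	V218I	FALSE	NA	0	1
B158	BRCA1	R282G	TRUE	NA	0	1
B158	BRCA1	E326K	TRUE	NA	0	1
B160	BRCA1	167 insA	TRUE	NA	1	0
B161	BRCA1	R213X	TRUE	NA	1	1
B161	BRCA1	R282W	TRUE	NA	1	1
B161	BRCA1	P151R	TRUE	NA	1	1
B162	BRCA1	NA	NA	NA	NA	NA
B164	BRCA1	258 delG	TRUE	NA	1	0
B165	BRCA1	NA	NA	NA	NA	NA
B171	BRCA1	R306X	TRUE	NA	1	0
C002	luminal-J	R248W	TRUE	NA	0	1
C002	luminal-J	R110C	TRUE	NA	0	1
C002	luminal-J	T55I	FALSE	NA	0	1
C010	luminal-J	NA	NA	NA	NA	NA
C017	luminal-J	K305X	TRUE	NA	1	0
C020	luminal-J	wild type	NA	NA	0	0
C022	luminal-J	NA	NA	NA	NA	NA
C025	luminal-J	P177L	TRUE	NA	0	1
C027	luminal-J	NA	NA	NA	NA	NA
C028	luminal-J	wild type	NA	NA	0	0
C030	luminal-J	wild type	NA	NA	0	0
C034	luminal-J	wild type	NA	NA	0	0
C036	luminal-J	wild type	NA	NA	0	0
C037	luminal-J	NA	NA	NA	NA	NA
C042	luminal-J	P190L	FALSE	NA	0	0
C044	luminal-J	wild type	NA	NA	0	0
C052	luminal-J	wild type	NA	NA	0	0
C057	luminal-J	P98L	FALSE	NA	0	0
C060	luminal-J	H179R	TRUE	NA	0	1
C060	luminal-J	T125M	FALSE	NA	0	1
131	BLBC	239_240delCA	TRUE	NA	1	0
135	BLBC	C242Y	TRUE	NA	0	1
164	BLBC	W53X	TRUE	NA	1	0
184	BLBC	183_184insC	TRUE	NA	1	0
215	BLBC	110delC	TRUE	NA	1	0
228	BLBC	IVS5-2 A > C (splice)	TRUE	NA	1	0
230	BLBC	E221X	TRUE	NA	1	0
238	BLBC	V173M	TRUE	NA	0	1
241	BLBC	R196X	TRUE	NA	1	0
268	BLBC	L252P	FALSE	NA	0	0
269	BLBC	N131S	FALSE	NA	0	0
270	BLBC	283insGC	TRUE	NA	1	0
307	BLBC	218delGTG	TRUE	NA	1	0
324	BLBC	I195T	TRUE	NA	0	1
326	BLBC	155_156del	TRUE	NA	1	0
330	BLBC	201delT	TRUE	NA	1	0
332	BLBC	Q286K	TRUE	NA	0	1
335	BLBC	R248W	TRUE	NA	0	1
367	BLBC	wild type	NA	NA	0	0
377	BLBC	255_256delTCA	TRUE	NA	1	0
398	BLBC	Y220C	TRUE	NA	0	1
6	luminal-H	wild type	NA	NA	0	0
107	luminal-H	Q317X	TRUE	NA	1	0
110	luminal-H	wild type	NA	NA	0	0
145	luminal-H	R273C	TRUE	NA	0	1
157	luminal-H	R248W	TRUE	NA	0	1
166	luminal-H	wild type	NA	NA	0	0
167	luminal-H	wild type	NA	NA	0	0
176	luminal-H	wild type	NA	NA	0	0
203	luminal-H	wild type	NA	NA	0	0
205	luminal-H	K132R	TRUE	NA	0	1
214	luminal-H	wild type	NA	NA	0	0
220	luminal-H	wild type	NA	NA	0	0
231	luminal-H	wild type	NA	NA	0	0
240	luminal-H	H179R	TRUE	NA	0	1
295	luminal-H	wild type	NA	NA	0	0
298	luminal-H	wild type	NA	NA	0	0
302	luminal-H	wild type	NA	NA	0	0
305	luminal-H	wild type	NA	NA	0	0
312	luminal-H	205delT	TRUE	NA	1	0
318	luminal-H	R110L	TRUE	NA	0	1
318	luminal-H	S127C	TRUE	NA	0	1
322	luminal-H	wild type	NA	NA	0	0
329	luminal-H	wild type	NA	NA	0	0
346	luminal-H	wild type	NA	NA	0	0
354	luminal-H	P177R	TRUE	NA	0	1
356	luminal-H	wild type	NA	NA	0	0
361	luminal-H	wild type	NA	NA	0	0
371	luminal-H	wild type	NA	NA	0	0
378	luminal-H	wild type	NA	NA	0	0
389	luminal-H	wild type	NA	NA	0	0
391	luminal-H	wild type	NA	NA	0	0
393	luminal-H	wild type	NA	NA	0	0
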