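A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.935	-1.017	-0.317	-0.317	-1.052	-0.678	-0.352	-1.25	-0.27	-1.168	-0.947	-0.317	-0.538	-0.317	-0.2	-0.632	-0.643	-1.215	-0.62	-0.573
C	-1.017	-1.107	-0.33	-0.33	-1.146	-0.731	-0.369	-1.367	-0.278	-1.276	-1.03	-0.33	-0.576	-0.33	-0.2	-0.68	-0.693	-1.328	-0.667	-0.615
D	-0.317	-0.33	-0.219	-0.219	-0.335	-0.276	-0.224	-0.367	-0.211	-0.354	-0.319	-0.219	-0.254	-0.219	-0.2	-0.269	-0.27	-0.361	-0.267	-0.259
E	-0.317	-0.33	-0.219	-0.219	-0.335	-0.276	-0.224	-0.367	-0.211	-0.354	-0.319	-0.219	-0.254	-0.219	-0.2	-0.269	-0.27	-0.361	-0.267	-0.259
F	-1.052	-1.146	-0.335	-0.335	-1.187	-0.754	-0.376	-1.417	-0.281	-1.322	-1.065	-0.335	-0.592	-0.335	-0.2	-0.7	-0.714	-1.376	-0.687	-0.633
G	-0.678	-0.731	-0.276	-0.276	-0.754	-0.511	-0.299	-0.883	-0.246	-0.83	-0.686	-0.276	-0.42	-0.276	-0.2	-0.481	-0.489	-0.861	-0.473	-0.443
H	-0.352	-0.369	-0.224	-0.224	-0.376	-0.299	-0.231	-0.417	-0.214	-0.4	-0.354	-0.224	-0.27	-0.224	-0.2	-0.289	-0.291	-0.409	-0.287	-0.277
I	-1.25	-1.367	-0.367	-0.367	-1.417	-0.883	-0.417	-1.7	-0.3	-1.583	-1.267	-0.367	-0.683	-0.367	-0.2	-0.817	-0.833	-1.65	-0.8	-0.733
K	-0.27	-0.278	-0.211	-0.211	-0.281	-0.246	-0.214	-0.3	-0.207	-0.292	-0.271	-0.211	-0.232	-0.211	-0.2	-0.241	-0.242	-0.297	-0.24	-0.236
L	-1.168	-1.276	-0.354	-0.354	-1.322	-0.83	-0.4	-1.583	-0.292	-1.476	-1.184	-0.354	-0.646	-0.354	-0.2	-0.769	-0.784	-1.537	-0.753	-0.692
M	-0.947	-1.03	-0.319	-0.319	-1.065	-0.686	-0.354	-1.267	-0.271	-1.184	-0.959	-0.319	-0.544	-0.319	-0.2	-0.639	-0.65	-1.231	-0.627	-0.579
N	-0.317	-0.33	-0.219	-0.219	-0.335	-0.276	-0.224	-0.367	-0.211	-0.354	-0.319	-0.219	-0.254	-0.219	-0.2	-0.269	-0.27	-0.361	-0.267	-0.259
P	-0.538	-0.576	-0.254	-0.254	-0.592	-0.42	-0.27	-0.683	-0.232	-0.646	-0.544	-0.254	-0.356	-0.254	-0.2	-0.399	-0.404	-0.667	-0.393	-0.372
Q	-0.317	-0.33	-0.219	-0.219	-0.335	-0.276	-0.224	-0.367	-0.211	-0.354	-0.319	-0.219	-0.254	-0.219	-0.2	-0.269	-0.27	-0.361	-0.267	-0.259
R	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
S	-0.632	-0.68	-0.269	-0.269	-0.7	-0.481	-0.289	-0.817	-0.241	-0.769	-0.639	-0.269	-0.399	-0.269	-0.2	-0.454	-0.46	-0.796	-0.447	-0.419
T	-0.643	-0.693	-0.27	-0.27	-0.714	-0.489	-0.291	-0.833	-0.242	-0.784	-0.65	-0.27	-0.404	-0.27	-0.2	-0.46	-0.467	-0.812	-0.453	-0.425
V	-1.215	-1.328	-0.361	-0.361	-1.376	-0.861	-0.409	-1.65	-0.297	-1.537	-1.231	-0.361	-0.667	-0.361	-0.2	-0.796	-0.812	-1.602	-0.78	-0.716
W	-0.62	-0.667	-0.267	-0.267	-0.687	-0.473	-0.287	-0.8	-0.24	-0.753	-0.627	-0.267	-0.393	-0.267	-0.2	-0.447	-0.453	-0.78	-0.44	-0.413
Y	-0.573	-0.615	-0.259	-0.259	-0.633	-0.443	-0.277	-0.733	-0.236	-0.692	-0.579	-0.259	-0.372	-0.259	-0.2	-0.419	-0.425	-0.716	-0.413	-0.39
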