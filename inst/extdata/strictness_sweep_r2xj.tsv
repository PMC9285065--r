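n_blocks	strictness	RDKit	CDK	cddd	QM	Dragon	PaDEL	alva_add	ECFP4	unity	MACCS	Morgan
11	-0.01	0.394	0.531	0.331	0.256	0.592	0.560	0	0.121	0.239	0.179	0.122
11	-0.03	0.634	0.753	0.416	0.484	0.630	0.571	0.608	0.188	0.309	0.467	0.187
11	-0.05	0.725	0.847	0.435	0.843	0.634	0.586	0.667	0.182	0.302	0.525	0.187
11	-0.1	0.767	0.816	0.426	0.758	0.634	0.586	0.761	0.177	0.317	0.585	0.182
11	-0.2	0.799	0.896	0.435	0.743	0.634	0.583	0.836	0.188	0.323	0.605	0.192
11	-0.5	0.865	0.931	0.452	0.944	0.634	0.592	0.929	0.188	0.343	0.631	0.186
12	-0.01	0.673	0.684	0.358	0.298	0.619	0.565	0	0.153	0.258	0.202	0.153
12	-0.03	0.632	0.779	0.419	0.578	0.633	0.582	0.641	0.172	0.327	0.499	0.183
12	-0.05	0.727	0.779	0.418	0.645	0.625	0.580	0.558	0.177	0.300	0.539	0.177
12	-0.1	0.786	0.780	0.436	0.667	0.624	0.579	0.744	0.166	0.316	0.581	0.165
12	-0.2	0.800	0.868	0.435	0.895	0.620	0.579	0.858	0.170	0.329	0.618	0.169
12	-0.5	0.865	0.926	0.454	0.945	0.638	0.594	0.929	0.188	0.344	0.642	0.187
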