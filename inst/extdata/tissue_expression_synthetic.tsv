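# Synthetic miRNA-by-tissue expression fixture (seeded draw, two planted
# expression programs); ids are the 16 distinct miRNAs of the packaged
# ternary table. Not measured data.
mirna_id	stomach	kidney	liver	spleen	bone	myocardium	muscle	colon	thyroid
miR-181b	2.992	3.06	2.919	3.034	3.104	2.022	1.85	2.027	1.967
miR-195	2.902	3.045	2.996	3.075	2.987	2.174	1.977	1.794	2.125
miR-214-3p	2.812	3.09	2.936	3.066	3.084	1.988	1.918	2.075	1.988
miR-647	2.981	3.057	2.956	2.891	2.963	2.049	1.868	2.001	2.24
miR-214	2.937	2.959	3.051	2.958	3.105	2.014	2.008	1.9	2.035
miR-130a-3p	3.109	2.971	3.113	3.118	3.093	2.031	1.989	2.258	2.095
miR-1	2.909	3.122	3.098	3.158	2.852	2.099	2.091	2.07	1.968
miR-185-5p	3.1	3.024	2.988	3.228	2.908	1.948	2.098	2.188	2.132
miR-103	1.96	1.955	2.043	1.793	1.992	2.919	3.094	2.952	2.816
miR-107	1.953	1.815	2.042	1.959	1.913	2.808	2.998	3.037	3.063
miR-133a	2.033	1.937	2.044	2.03	2.068	2.861	2.928	3.01	2.982
miR-2499	1.959	1.914	1.98	2.07	1.992	3.043	3.03	3.035	3.038
miR-30c	2.056	2.151	2.03	2.099	1.987	2.971	2.91	2.923	2.977
let-7e	2.066	2.274	2.069	1.972	1.961	3.228	3.139	3.11	2.985
miR-143	1.94	1.973	2.237	1.808	2.002	2.884	3.067	2.931	3.069
miR-221	2.07	2.128	2.108	1.883	1.887	3.124	3.001	2.98	2.826
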