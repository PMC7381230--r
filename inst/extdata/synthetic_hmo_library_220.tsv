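glycan_id	composition_label
hmo001	H3N1S1
hmo002	H4N2F3
hmo003	H6N4F4/H7N5F2
hmo004	H5N3F3
hmo005	H4N2F2
hmo006	H4N2F2S1
hmo007	H7N5F3/H8N6F2
hmo008	H6N4F2/H7N5F1
hmo009	H7N5
hmo010	H4N2F1S1
hmo011	H5N3F1
hmo012	unknown
hmo013	H5N3F1S1
hmo014	H3N1F2
hmo015	H5N3F2
hmo016	H9N7F4
hmo017	H10N8F4
hmo018	H2F1 (3-FL)
hmo019	H5N3F3S1/H6N4F2S1
hmo020	H3N1S1 (LSTb)
hmo021	H6N4S1
hmo022	H4N2F3S1
hmo023	H3N1F1S1
hmo024	H3N1F1 (LNnFP V)
hmo025	H6N4F3
hmo026	H5N3F2S1
hmo027	H5N3F2S2
hmo028	H6N4F1S1
hmo029	unknown
hmo030	unknown
hmo031	H6N4F5
hmo032	H5N2F1S1
hmo033	H8N5F2S2
hmo034	H3N1F5
hmo035	H3N2F1
hmo036	H9N8F2S2
hmo037	H5N2F3S1
hmo038	H10N7S2
hmo039	H3N1F1
hmo040	H3F3
hmo041	H3N2F3S1
hmo042	H3
hmo043	H11N9F4S1
hmo044	H6N5F1S1
hmo045	H3N1F3S2
hmo046	H5N4F1S1
hmo047	H2F3
hmo048	H6N3F3S2
hmo049	H6N3F1
hmo050	H10N9
hmo051	H8N7F1
hmo052	H2
hmo053	H4N2F1S2
hmo054	H2N1S1
hmo055	H3F1
hmo056	H10N7F2S1
hmo057	H9N8F2S1
hmo058	H11N8S2
hmo059	H8N5
hmo060	H8N6
hmo061	H5N2F1
hmo062	H3N2S1
hmo063	H5N4S1
hmo064	H6N4F2S1
hmo065	H12N9F3S2
hmo066	H8N5F2
hmo067	H10N7F2S2
hmo068	H10N9F4S3
hmo069	H3F4
hmo070	H10N9F4
hmo071	H12N11F1
hmo072	H10N7F1S1
hmo073	H3N2F2S1
hmo074	H5N4
hmo075	H5N3
hmo076	H4N3F1S2
hmo077	H11N9
hmo078	H10N9S1
hmo079	H4N3
hmo080	H2F1
hmo081	H9N6
hmo082	H10N7F3
hmo083	H6N5F1
hmo084	H10N8F1
hmo085	H4N2F2S2
hmo086	H4N1F1
hmo087	H6N5
hmo088	H3N2F2
hmo089	H8N6S1
hmo090	H3N2S2
hmo091	H6N3F1S1
hmo092	H7N5F1S2
hmo093	H9N7
hmo094	H4N3F2S2
hmo095	H12N9F1S1
hmo096	H12N11F1S2
hmo097	H4N1
hmo098	H3F5
hmo099	H8N6F1S3
hmo100	H9N6S2
hmo101	H12N10
hmo102	H12N9
hmo103	H8N5F1
hmo104	H10N8F2S1
hmo105	H2F4S2
hmo106	H9N6F2S1
hmo107	H2N1F3
hmo108	H6N3S2
hmo109	H10N8S2
hmo110	H2N1F2
hmo111	H11N10F4
hmo112	H10N9S3
hmo113	H2F1S1
hmo114	H9N7F2
hmo115	H3F2
hmo116	H5N4F2
hmo117	H6N4F1S2
hmo118	H12N11F2S2
hmo119	H11N10F3
hmo120	H8N6F1S1
hmo121	H10N9F3
hmo122	H7N4F1
hmo123	H5N3S2
hmo124	H9N7S1
hmo125	H7N6F3
hmo126	H4N3F5
hmo127	H9N7S2
hmo128	H6N3S1
hmo129	H10N7
hmo130	H3N1
hmo131	H5N2S1
hmo132	H12N11F5
hmo133	H4N3F4S1
hmo134	H12N11S2
hmo135	H4N1F2S1
hmo136	H2N1
hmo137	H5N2F4
hmo138	H12N11F2
hmo139	H7N4
hmo140	H12N10F2S1
hmo141	H8N5F5
hmo142	H7N4F2S1
hmo143	H12N10F4
hmo144	H4N3F2
hmo145	H4N2S1
hmo146	H7N6F5
hmo147	H11N9F1S1
hmo148	H6N5F4
hmo149	H7N5F3
hmo150	H12N11F3S3
hmo151	H11N10F4S2
hmo152	H12N9S3
hmo153	H10N8F2
hmo154	H3N1F1S2
hmo155	H3F1S1
hmo156	H12N9F2
hmo157	H2S1
hmo158	H2F2S2
hmo159	H11N8
hmo160	H2N1F1
hmo161	H11N8F2
hmo162	H12N11F3
hmo163	H12N10F2
hmo164	H7N6F2
hmo165	H9N8F3S1
hmo166	H10N7F5S1
hmo167	H12N9F1
hmo168	H10N9F1S2
hmo169	H7N6F1
hmo170	H12N10F1
hmo171	H3N1F5S1
hmo172	H10N8F1S1
hmo173	H10N9F1
hmo174	H7N6S2
hmo175	H2N1F4S2
hmo176	H7N4F5S1
hmo177	H4N1F1S2
hmo178	H6N5S2
hmo179	H9N6F1
hmo180	H12N10S2
hmo181	H7N6F4
hmo182	H2F5S1
hmo183	H5N2F5S2
hmo184	H12N10F4S1
hmo185	H10N7F5S2
hmo186	H5N4F1
hmo187	H4N3F2S3
hmo188	H9N8
hmo189	H2F2
hmo190	H5N3S1
hmo191	H9N8F4
hmo192	H11N8F3S2
hmo193	H7N4F4
hmo194	H5N3F1S3
hmo195	H11N8F1
hmo196	H6N5S1
hmo197	H4N2
hmo198	H8N5F4
hmo199	H8N6F3
hmo200	H10N8S1
hmo201	H4N1F2
hmo202	H12N10F1S3
hmo203	H7N6
hmo204	H11N8F3
hmo205	H4N1F4S1
hmo206	H8N6F4S1
hmo207	H7N4F5
hmo208	H9N8S2
hmo209	H12N9S2
hmo210	H4N3F1
hmo211	H5N4F2S1
hmo212	H9N8F1S3
hmo213	H9N6F2
hmo214	H4N1F3S1
hmo215	H11N10F1S1
hmo216	H10N8
hmo217	H4N2F4S2
hmo218	H9N8F1S1
hmo219	H5N4F4
hmo220	H11N9F4S2
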