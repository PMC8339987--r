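id	text	answer_type	stage_label
1	Whether the tumor can be visualized by imaging or bronchoscopy?	boolean	TX
2	What is the greatest dimension of the tumor?	numeric	T1-4
3	Whether the tumor invades the lobar bronchus?	boolean	T1
4	Whether the tumor invades the visceral pleura?	boolean	T2
5	Whether there is an atelectasis or obstructive pneumonitis that extends to the hilar region, either involving part of the lung or the entire lung?	boolean	T2
6	Whether there is (are) associated separate tumor nodule (s) in the same lobe as the primary?	boolean	T3
7	Whether the tumor invades the great vessels?	boolean	T4
8	Whether the tumor invades the vertebral body?	boolean	T4
9	Whether there is (are) separate tumor nodule (s) in a different ipsilateral lobe to that of the primary?	boolean	T4
10	Whether there is regional lymph node metastasis?	boolean	N0
11	Whether there is metastasis in ipsilateral hilar lymph nodes, including involvement by direct extension?	boolean	N1
12	Whether there is metastasis in ipsilateral mediastinal lymph nodes?	boolean	N2
13	Whether there is metastasis in subcarinal lymph nodes?	boolean	N2
14	Whether there is metastasis in contralateral mediastinal lymph nodes?	boolean	N3
15	Whether there is metastasis in contralateral hilar lymph nodes?	boolean	N3
16	Whether there is metastasis in supraclavicular lymph nodes?	boolean	N3
17	Whether there is (are) separate tumor nodule (s) in a contralateral lobe?	boolean	M1a
18	Whether the tumor with pleural nodules?	boolean	M1a
19	Whether there is malignant pleural or pericardial effusion?	boolean	M1a
20	What is the shape of the tumor?	text	NA
21	What is the density of the tumor?	text	NA
22	What is the enhancement extent of the tumor?	text	NA
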