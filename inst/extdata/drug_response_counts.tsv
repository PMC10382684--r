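drug	cohort	ns_train	nr_train	ns_test	nr_test
docetaxel	GSE6434	564	286	10	14
erlotinib	GSE33072	28	342	11	14
sorafenib	GSE33072	117	286	21	16
cetuximab	PDX	40	837	5	55
erlotinib	PDX	28	342	3	18
gemcitabine	PDX	680	186	7	18
paclitaxel	PDX	284	115	5	38
cisplatin	TCGA	275	575	60	6
docetaxel	TCGA	564	286	8	8
gemcitabine	TCGA	680	186	21	36
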