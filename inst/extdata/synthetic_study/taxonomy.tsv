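otu_id	lineage
OTU0001	Bacteria;Actinobacteria
OTU0002	Bacteria;Actinobacteria
OTU0003	Bacteria;Firmicutes
OTU0004	Bacteria;Proteobacteria
OTU0005	Bacteria;Other
OTU0006	Bacteria;Other
OTU0007	Bacteria;Firmicutes
OTU0008	Bacteria;Firmicutes
OTU0009	Bacteria;Proteobacteria
OTU0010	Bacteria;Proteobacteria
OTU0011	Bacteria;Actinobacteria
OTU0012	Bacteria;Actinobacteria
OTU0013	Bacteria;Firmicutes
OTU0014	Bacteria;Actinobacteria
OTU0015	Bacteria;Firmicutes
OTU0016	Bacteria;Proteobacteria
OTU0017	Bacteria;Proteobacteria
OTU0018	Bacteria;Firmicutes
OTU0019	Bacteria;Firmicutes
OTU0020	Bacteria;Actinobacteria
OTU0021	Bacteria;Proteobacteria
OTU0022	Bacteria;Firmicutes
OTU0023	Bacteria;Proteobacteria
OTU0024	Bacteria;Firmicutes
OTU0025	Bacteria;Firmicutes
OTU0026	Bacteria;Firmicutes
OTU0027	Bacteria;Bacteroidetes
OTU0028	Bacteria;Other
OTU0029	Bacteria;Firmicutes
OTU0030	Bacteria;Actinobacteria
OTU0031	Bacteria;Proteobacteria
OTU0032	Bacteria;Proteobacteria
OTU0033	Bacteria;Actinobacteria
OTU0034	Bacteria;Firmicutes
OTU0035	Bacteria;Proteobacteria
OTU0036	Bacteria;Proteobacteria
OTU0037	Bacteria;Proteobacteria
OTU0038	Bacteria;Bacteroidetes
OTU0039	Bacteria;Actinobacteria
OTU0040	Bacteria;Firmicutes
OTU0041	Bacteria;Proteobacteria
OTU0042	Bacteria;Firmicutes
OTU0043	Bacteria;Proteobacteria
OTU0044	Bacteria;Proteobacteria
OTU0045	Bacteria;Actinobacteria
OTU0046	Bacteria;Proteobacteria
OTU0047	Bacteria;Actinobacteria
OTU0048	Bacteria;Actinobacteria
OTU0049	Bacteria;Proteobacteria
OTU0050	Bacteria;Actinobacteria
OTU0051	Bacteria;Firmicutes
OTU0052	Bacteria;Proteobacteria
OTU0053	Bacteria;Firmicutes
OTU0054	Bacteria;Other
OTU0055	Bacteria;Firmicutes
OTU0056	Bacteria;Proteobacteria
OTU0057	Bacteria;Firmicutes
OTU0058	Bacteria;Proteobacteria
OTU0059	Bacteria;Firmicutes
OTU0060	Bacteria;Firmicutes
CONTAM001	Bacteria;Proteobacteria
CONTAM002	Bacteria;Actinobacteria
CONTAM003	Bacteria;Actinobacteria
CONTAM004	Bacteria;Actinobacteria
CONTAM005	Bacteria;Proteobacteria
CONTAM006	Bacteria;Actinobacteria
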