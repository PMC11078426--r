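>muty_query2_synthetic synthetic second query, ~62% identity to reference
VWAFDLGSVHGYSRCDEHMPNTRECRKEVLRNYSHAYGLRDYEHPAFQVAEKFGCDIEYY
HWYDLCRAKDEYNEEGYQQCPDTKNCYYHAEQITSWSTLLYLNSWKKICMPDQVHNNWLA
RNHWTYRWFHWYTQRNIHCMKPFDGNVGRSVNTATLPCCYAIWQYNRIESSVFSDSNTNG
LEMHFKVDCGRCHKAMTGCHMCYCCLSCRIGNFHFYAMHQHQKTLHLLRWNGYNNMKRDN
DNLSYENHWATLQNGPYRQERGAGLCEFPPANYDSRHTIINMTICGWFYSADSHLQPGTP
MTNNHCFSHESTFSENFVWWYRPQVACTKHPTATMHHQFTWIAVFQNCKVGYESYYSAGC
CTWAKFTECEMC
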