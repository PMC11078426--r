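>muty_ref_synthetic synthetic reference with planted motif anchors
VAAPNFGSVHGMSRCSHHMPNTRECRKLKERVESWACPLRDYEHGAFQVARQPGCDMVYE
MWYDDCIAKDGYIEIGYQKCPSEKNCYYHMEVINSKSFQLYLNWFKGICMIDPAHNKWLA
ANHWGYRWSAWDTQRAIHCMKVMDGNVARGFKTATLPCCYAIWQYNMLNVASFSDIMPNA
EPMAAKIDCGICGTATTQCHMCYEYLMCRIAWPHFYAMFTHQKGRHNLNWWGIYTPRKFN
DNVGYENHMATLCPDFYRCERGAGLCEMPPAPYHFRHTNPNMTIFGKFYDAMSHFIYGRP
MWNNHGFSHEEIFCENFVNWYRPQAACHPHPTAYMVHQFGNDAQPQNFKVGYIEYYSAGD
WTWEKHTECEMC
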