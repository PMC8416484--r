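>example_pos_001 synthetic positive PrLD
LKIFELEVQKSGTQLQLGLDCLFKQPVNQQDRGALQQEIREIRLQGYSNLQGLISWLWLH
ASALIVADINQRGVDLW
>example_pos_002 synthetic positive PrLD
FQKNSLNGTMTHPEKLHWQCAFDEEWNVDMKPVLRINGQAKLVKHSLQHDSMTSSGEHGS
PDGHHLRNQNKLSVQTIAMTNS
>example_pos_003 synthetic positive PrLD
NCAEGKQQNVHIWFCCLVFLIFQSADDQHCGAARFHIKHQE
>example_pos_004 synthetic positive PrLD
LTFNMQHKPFWLWTLYFVFLAGGVLLGMKQQKVTPARPEWQTSRSEHLSGQSVSSHLLSY
HLCGLGNANSRPH
>example_neg_001 synthetic negative PrLD
AALTGQSAAPIPNKGYEANTDTQSKAPNGTSAANVSEPPNLAPEEQQNGSYSVAANPGTS
TNNDQPQRQGPPLSGPSQPQAGINKLLQL
>example_neg_002 synthetic negative PrLD
TAGAQQDYYQYQDQTSRQSAHDNQGENGGQYYNNYFQNSEQQNPSNQYYQHNNQAQGDLN
QGVDTISNAWNDGNYSDT
>example_neg_003 synthetic negative PrLD
SQGSQANNNMLSAAKSNGSWNQNNSQNPSSGNYAQQTQLNAGFVNAELSYSQSSAKANSQ
>example_neg_004 synthetic negative PrLD
EGGDNTQNQLNAQAQNNSHAPNPDPPYGQNQAVNVIQQQNPTFGSKGVFFHQQQNNMNNP
PAGEQSQRSTQPGPPANDQHAGSNQNGSN
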