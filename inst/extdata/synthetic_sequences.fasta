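>sp|HP0001|PROT1_HUMAN synthetic fixture protein
YQRPGNGPGKYVGWPESDLERDELGTFDNMHGMPHRKGIFGSWCENHSGSWWGEIMQKED
STLMKWATAKLSRHTGHHVFLVGWNWMWLRVRWGCTSHPLG
>sp|HP0002|PROT2_HUMAN synthetic fixture protein
MKRVAMDIQKMQYDITEKFLHGALIWKNPCWRALQRAEFGPPRPLDNRNWGMWSEGPVLH
HQMDGNFKFCMNYLPTAYMLEIQSERFQNWIWKPCDFGVTSFRVNNNRDGPWGFRSTTNF
TCEFFIVIIANHPA
>sp|HP0003|PROT3_HUMAN synthetic fixture protein
NCQLINPAHYWISQIYAHQDTEDCDWSPHRVQAASVRHITVLHTTGKDMIYRNIAPLKCR
IPNKSIDRAWMVMMIFMDLLKYMQVLPDHIQAITYRPNFDGKGCQEPSYSHQHWFYHV
>sp|HP0004|PROT4_HUMAN synthetic fixture protein
RVVDKDTIDSKPKFNIMAQGAMICWEVTDLIRLWCHWTLTLTHWGHCMTWAMEASARQNC
AWAYFEDRKKFSDSTILASWRMTFTHQPRNCDSRMFLCVDEVCVLTFFAPHMFAAIEMAG
GECEWGTHVY
>sp|HP0005|PROT5_HUMAN synthetic fixture protein
NMRHPNIKTLDDRLSIPIDEWYVYKNNWLEMPNHHFMMWMVEKPGWLEDQYRNNGQWLTD
NVYNYRPCMREVSSDVGQEITDQWFILEWWTAYYKMIKYLKRHIDSPDLAWALTMWGCYK
RMWYARQPIIGNCIKPRQNRVHMTAPAGWYGTWETSS
>sp|HP0006|PROT6_HUMAN synthetic fixture protein
QTEVPFYTQCKNVMGNLRILFMEKQFMVVVMKFKTFNMPMQRCQSWFGFWIAFLGAMKLK
HARKNDVEHVVKNGERWVEQDLYSAYKRLRCGVDWCDPTPSIEIWMYVSCQTKMSPYNLM
LQIQTKHVAISYDDHLIQQRFSQKMSMLVSRISYPDFWYGVKKWFQNCGNTLNMLSMQYT
IVMCHLIFYEENQDKACREDLGYFS
>sp|HP0007|PROT7_HUMAN synthetic fixture protein
KCSLSVTDVDRSGVWWGPIEPMSISPDKMNKVWMSVAPRHTLSAGMQKWKERRYDIAVTL
CAYCPLHASCVLILPTPGFESNKWKPQYNNTMKYIYQHEDCRINKWASVSAFIEGPSFVG
PSFRRMSYIYECNDFERFSDVRELWDIHYMGYHA
>sp|HP0008|PROT8_HUMAN synthetic fixture protein
TKNNWGLHKWRNPKYVSTWAQGLWADFCHVPMTHGMHTPKEQRIFRVFWNIHTAIIDQHC
YVRGVSSRQYSLRQWKERPYSGRMDCCLKEHCYASGIASWTCVWQVDIGPCKAFGHACVG
IEPHHGSSMNCNAWIGWPQFEHLSIDSSNFEIYRKEDYTFDNQFHKHNHDNRTYVIHWFF
ADLEINRKLVITFYRFQG
>sp|HP0009|PROT9_HUMAN synthetic fixture protein
STHEPSRFQMSCVTSIDRQNCPMMWFMDFGVPENMDINAILNCTHSDYMFPVKGVFHMGV
SGYYIKGWEQPFVPWFPGDFHAWYELARSHDSRPKSAYHGASP
>sp|HP0010|PROT10_HUMAN synthetic fixture protein
HSLHCLSQMARSMLQECSMEAHLLIGRRMWYILKESSPSDHCWADEIDPHWTANMWHMNI
HGHLFHLNVMSHGDNTICCILNKVWGNTQTGPGVIRPRICPAERHGMLILAVDTKGIHVS
SARLTFMRNVQADITTMIRRMI
>sp|HP0011|PROT11_HUMAN synthetic fixture protein
CGINMFAFHAYAACTFQHKHSRFPFVKQHNLSQSVQKRTLRTIFSKDYPFDMSTEGRDPY
C
>sp|HP0012|PROT12_HUMAN synthetic fixture protein
KDFQRDDHITSDMPCGSTWEHHARVMYFKYHVMNYNNYCQRVTPFYLIEMFVKTMHNIDW
SCSASGPH
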