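>IsoA_syn|isoA
DENDSLIRGQEMQVNLNTLFNWHLYPEFCLRKDVNNDCFNTKSDIRLECGPKTDFDMIPS
CYQHEVHASRFCKFMHGQNASSYEHTQGASLLTATWEMTVGHDHKCLKVYYKKPRGALNT
WFWTGYEQPPVVMYWNLELNLTKRAVRKNIRDCCQLQLDSTPGNGWHEQSEWSSYTFQPE
SVDIWTPDMFNQDWGGQMYRSLIKDNWQASGWQIKEIGIGVWRAMWDVFRCFFTMISHEH
MHKNGCNYQMHVAWFAPFTEAIAWYPINDPCNWGYCQDEATWKFMAEWHNCDIPPGWWYT
MFVMIMCMWVNFRKICWNWQHHHEQPEADKQKQYNGAEWHSCRYNADIKVFYTFEVKSPQ
FVEQYVIKACHHEDNIMWQWMENAVADHNWMVHWFLHYAMPAVFYNFQMVYMQQSHKPWR
MSLERSFCSSQQRIIVMMCSNSDFCYKLKNNTEVVIPDEGSLIMEWSFLYACNDNWFMAG
HAIFEQCPPNMSNAKPY
>RecA_syn|recA
ALFVETEHPDSIMQLCWTWVYNFLFEGHCMSKMSFMHEGELNQNCNLPMGAICIHDEGAG
GIWFPLQDGPSRKDWQPTYYEQGWNRWKGTSFWWQMRNYFEFLEEVWLTDCMFWGKHHQF
FFFNAERMRWIVNSGEDCANNCIGGVSRYNKNLAKMDSVDQNLKTLAQTKQLVVCTTPMA
PWYGPTHAGHHYYVGPMPTEHHAKTHWKEFSWSYSAHAVKTMTQSWPWNGGDMQFGCPTV
AVNTYTKASCQWCMPLIYCFYFVHWCRIGDTAHHESIHVCPEASYWYIILYNHWEMCGYS
GDTTQHLVIGKMYQGWRGESLNIFHWFPNVGGWQSHANPHLDMYYSHIQVTPT
>IsoB_syn|isoB
VISRTMNERGTIGAKATENSFDQWRPVWNETMKFDYQFHLPKVSCSKIAFNWLQCCRVQD
YNWWPEKMMHWCTMAPWWCFAQCPKREQGTWANSNYKVPGSVGPVPTKKTTKPYISGNHW
LETAIHPQMWQEHTVWCGEKCSNISNKAVSMMFKTRAIRAKWDEPDSPHRNTKVTKEPTS
ADPDPMRATIQEFKCILQLEDGLSNISINFFARHTWPKGSGSANSNRTDRTEQDKSCNGW
CGRALMVWERVSHPMDYAVRMVTSLRTSRITYINENFRAPQQIYLCELKWWNVWDISDQN
EHAFKWTLYFKGGYQFMYAHENNKIDIHFHSSMVNGHFHI
>IsoC_syn|isoC
YSSEKGRQDENARCGLVQLAWEPWNYNRPHIRDHGPNACKHISNWEYGLIGWSLETFWPW
FTRVDFDNQKWWCRIDQVTEWCMKFVHMFGQPMKHHFFNAHYSPGSQSPFEESVFRGSGC
>IsoD_syn|isoD
VTQTAMVFSTNHQTPFQKSACHDMGKTKVAKCDCHMATKYDIGQLYEGLEPIISLNMSTS
YSCDVDEPHNTEYLIPATDLIQRCGNAKHGKVGDEPGQQKIEY
>IsoE_syn|isoE
CYWQFNVYRHLYYFPSQGCWYQPFRIKRQDNMNLPEYAMFEPTWTVVRGFPLTMSPAPEQ
TPENWVVPMYKRCNGIVPCPGMILPLYRPGRMTMMDNKFISSIYITYSSDCEVATGHNSF
VAQAHSSIMWAWTQDACLRCCIGENNYAHGSGLFIILEGDKFYHSKGPPVYRIFVPVKYH
MDHKVAQCTFAEHENADSRDLHHVNMNGWLFVCGSEPTCCKGCYEWKMWTDTIGAFQGFT
PSYVFIFWPILSPIHQNEPGLDQYSGQYNCLMIDLAKHGYCAYMHHSHEGMNKTEYRQSE
FKHQVGQGDMLYAEYWCNVGLWCTCKMPMILAGCWAAMEQDII
>IsoF_syn|isoF
YIMSQNDHVHCEWRKNRGINRTVGICCVRQQWTYTFGHWVANHTLSETMMHQCIGELNKK
VLVDRCTNCRREPNAECIVVMIAFDTQNFRCTHSHRQEEFCHPEKRPIKGND
>IsoG_syn|isoG
RYLNVHITMIQRPTVLKSCDVLHGCNWCKSNWQWEFNTCLKWMETRSNNHFNTWWHVPEL
YAFHNKGDCCDSPAELTCISTCNFYFECAESQCFRPPMDIYQFKQAALTQPEREKGDSHM
TDVSQASKFYVHFWVFMPTRTARLKMFSPVKHKNEYLKEMQHSGYIAWAPYIMIIRVARV
>IsoH_syn|isoH
VQHCNDEKQHCGSCYRNVAECSSYYNVNGWCQGTSVRIDLLWCCHCRSKWVATTDCHSLN
CVNESMFKQKLTTNNFGESEVARVFNFKMDLYKQFALAVMIDKCMKRTNFYIVKRHKYGP
KLTEPLCVDQKLDFDVHECYWGFCQKHRTHISVYWRQKCFHFKKPHDIEFDNDALTHTWF
PHNWWAVSSGGWADQYTQMSMHDYDVEPLNCAMLFRGDCMYNIHMADLGEGQPYKDGIIC
MKTHVKDLCNFIIFICRTNVWKNFKMNWKKSRIGDYMYGH
>IsoI_syn|isoI
TGNLGGPTFNGPPNWESFKHTYCRFFVYGAPLQFNAVIGYPAPRCHFTIPVRATMESVFA
YSKSWHSVEPFLTYIGNAMWSHITDDNEGMQVASEKPQCNQVWLEKLHMMYGKPNCPHES
GTPPRQYGATMIELAMTMMGEPMFGKCGVQ
>IsoJ_syn|isoJ
FRIRDFATKRMGEFYRECFPNHQYPQHYYFTGILIMTVGDAAKGYYPRKNAHQRQCSWSS
TMMWPGVHERKHQACEINDTRLYKKGKENQVWEGTFQKCYGMMIYKIIYVMHPMEEGENK
QTLFDTIWNNWWHITCNQYWNFVGGIMNCIIFLWKMGKVPWRCMTLLIKHTGEFPVDSPF
GYYSFVSFAWQDDAMFINHCMNLAYLWSLEGAAVPVMHVHPMSLEHCLADGIPNKSIQWW
YLLGVSYMFGDEMSYLKVEY
>AldH1_syn|aldH1
VNARCDHWFPKQYRYKCYGDDTTRYACEFSQWKRPTWEEKGEFYDIEICFRCEMMGRYLP
CIEAPDCWVRYYLWVEICKNCGCKCKYWNSAHWNTCCIGEWHFIFAWLQSFHNNDLIPLQ
YFLMEYWWTICIALWAPQQNYCCMPDHSQNNLYPCWVQNHNISFWVGNSAMDRQKQHYYD
HSKITHTYQQGHTQAYRSFPPKNQKTIRLVRWWSINYTFTCMEGKTHPFWGGSFPDYLWS
NGIINAVADTQPTHRMDRAERNCFPGRKGSTEVKYNFADLIFSQQKTHEWHAQADLENGG
DFFALRMAQIFAIRVWGYEEHTPCRPSKKAVVDFWDLKKHKLITNLATGTRRRCPHLFRN
NGWNIFDVHSAAPRTPIANHHQDGRPRFNDEFVWWRPVYGCNPMDLIPCLYHFSSFDRVA
EIKGMQCVESIKWWVVACYLLKQNPPVAIHGLNNAWIHIANYETNWFLKGKQFIRQMARN
VAFFLHDFQDWCMKTCFTCV
>AldH2_syn|aldH2
HAKWLIKVSQEMGTDNSFFTVSFILYCLTDIFYEGTSAPSQDDKYPRFSAYPMDDEKIKI
CHAQIYSCHSAPKCMESSEQEFRVLNQKEPTFFMMNQRFRMCKWMPLCWGRRPWDHACPK
HFWRHPGKWMEFFCDSVFAHEGRWTYGWDLSLDWMNVHAFHMIRYCTAFKKLQATVMPMC
PHNDHNPWSACMIQVAQNRMIGNECLWVAEQTINRGGKFLHWAGSAPHVYYKDHPDIISG
IEWCLHRSRTSSRGMYAYINAPCFCEYGCEKSINMDESWHDRIDLSCHRCRICAQLIVMD
HVPWHRADTWMWMQIWHFHGWKWWMLMSGQSTWKFANLIHPTTECTNCDHHHQGNNDNLD
NEYTDKKHVCSIRSFDMWSSAPEWDAAKDGVMSKNMHATTWIMLPGEMRPKDWILDNTCI
CPCVYSFHQWTIPMNIIHLAERDWQSFHRFYCRVYERGSLMDPSLHYVVCTHTKTMVGMP
>GshB_syn|gshB
SYCYYWYEWWWDAGLEGMMYGYPTSHFFRRQDWGGNPWVCMVEVRPYRCVKYPVQMCCVN
IILNQWRYVTFRLIWHFVMNHTWCLRIKTVGVAKWRPAFLLMIMRILGREFEPRVWYNFW
MNMMFWRLPYWQLDFDKFPPNSCTCNEGGPMDREASSSVQCWMLIALVKTACPVYRCVLI
GWPYIQPMDHINRQYGPSKASKARMTQVEEAWSSAFISKFKSKKDVWIAKPWHGNHTLSR
YVDYDTEDESTYRSNSTSQWTQPNIQDATLHSMIKLEQVRQHHIFQSYWWHWPCDCWNVP
RVEKTLLQSL
>GarB_syn|garB
PNDQQFRVQIQGEIGKPRTVHHAWQPHGCFQKEKQPCPAGWKHKVVWNGVAKYLMDSYMY
VLKKITMAQTIISVARQFRNGDHRADHHMMVVDDFKPWGNYKPIVIPQAFSCWSPCTQDA
APSYTMAAGFNDCYTFFGFTRKMKIRMYVYHTEAGEAFCFDDRPLQYWPGDDDLTYMTTY
QLWHTWYESNYMQDSIDQWPEWLFAECPFIKYEGYKILPGTDSRNSAGVSHDGLCWRPHI
QQLRQHCECLNSIRCYFKHRIAKFRSVWRDLCCISPHCDDTSVSEDFNQSEGRFEQGSHA
GEFHPAMMWSDLLWHQHPCIYRGSRQVDLIFQIPCGGSMNMYGQDCTTMVDHKRVNAKMQ
DNMKVCVKPNNCIDMAPHWNYAWMNNWETWSKTLLYTDRQLGLRCIQPDTMKPGSINYHS
GVWGKGVYKHMRKVEASWHMVMTYLIQKWQ
>CoADSR_syn|CoA-DSR
DGQTGACLPSDGQITARLQDSNSHVRWKFQIWITWIEVWNAGNNRMSFHIPDEVYFAGSK
MGNTWWGLWFTRWYSNHMGQFHQVEQPRAYHDKRTDAYHEQKKNDHTTEFCEDQPWLTYT
LGHEWEMCDIHHTWIMKHCHSYCGNYRGHQDCLTWERKGCNCGDTYYVNGHLIVKHVRWQ
LIEHHGGKKVFMRYYHSWMMVFWDRRQQIVTEYWVEDNMMACCKGIQAGNCCLYYYGEEL
RTEDRMHPTKNMILQKWPMADPMKFMHFDILNAEPPFFQDIIFLGLVDRMSWFTYLVTEQ
KYYKVSWMIVHACPTAIQTLTISQPCYRPLPVWRPTVDVFPEALRDTVDIVITRPRHKWG
RYNRGHQSILLHQTFVDYGKWKELYSRWRRGFLPFPNGMNMWHYQDTTENWDSQSIVFHY
FDLWFDSHQYKWYWFIDDWG
>IsoA_syn_v95|isoA
CENDSLIRGQEMQVNLNTLFNWHLYPEFCLHKDVNNDCFNTKSCIRCEMGPKTDFDMIPS
CYQHEVHASRFCKFMHGQKASSYEHTQGASLLTATWEMTVGHDHKCLKDYYKKPRGPLNT
WFWTGYEQPPKVMYKNLELNLTKRAVRKNIRDCCQLQLDSTPGNGWHEQSEASSYTFQLE
SVDIWTPDMFNQDWGGQMYRSLIKDCWQASIWQIKEIGIGVWRAMVDVFRCFFTMISHEH
MHKNGCNYQMHVAWFAPFTEAIAWYPINDPCVQGYCQDEATWKFMAAWHNMDIPPGWWYT
MFVMIYCMWVNFRKICWNWQHHHEQPEADKQKQYNGAEWHSCRYNADIKVFYTFEVKSPQ
FVEQYVIKACHHEDNIMMQWMENAVADHNWMVHWVLHYAMPAVFHNFQMVYMQQSHKPWR
MSLERSFCSSPQRIIVMMCSNSDFCYKLKNNTEVNIPDEGSLIMEWSFLYACNDNWFMAG
HAIFEQCPPNMSNAKPY
>IsoA_syn_v85|isoA
DENDSLIRGQEMQDNLKTLFNFHQYPEFKLWKKVNNDCWNTKSDIRLECGPEIDFDMIPS
CYQHEVHASRFCKFQGGDNASSYEHTQGASLLTATWEMTVGHDHKCLKVYYKKPRGQLNT
WFWTGYECPPVVMYWNDELNLTKRAFRKNIRDCCQLQLDSVPGNGAHEQSLWSSYTFQPE
SVDIWTVDMFNQDWGGQMYTSWIKDCWQAKHWQIKERGDYVWLAMWDFFRCAWEMTSHEH
YAKNGCNYQMHSAWFAYFTEAIAWYHINDPCNWRYCQDEQTWKFMAEWHNCDIEPGWWYS
MFVMIMCTWVNFHKICQNWQHHHEQPEADKQYQYNGAEWISCRYNADIKVFYTFEVKSPQ
FVEQMDIKACHHEDNIMWQPMENAVASHNWMCTWFLMYDMPQVFYNFGWVYMQQSHKPWR
MSLQHSFLSDQQRIIVMMCSNVDFCYKRKNNTEVVIPDEGSLIVEYSFFYACNDNGFEAG
HAIFEQCPPTMSFAALY
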