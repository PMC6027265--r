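time_h,biomass_gDCW_L,glucose_g_L,lactate_g_L,succinate_g_L,acetate_g_L,DO_pct,co2_evolution_Cmol_L_h,event
0,0.392377882595575,58.1239483177716,0,0,0,100,0.00314908871060857,
0.25,0.444310130281161,60.9243697487609,0.00119875808323706,0,0,86.4061661216229,0.00350963006249042,
0.5,0.476254096919389,59.5610302046192,0.00252910809985805,0,0,70.8852059364078,0.0040768995192296,
0.75,0.566151896544265,64.1633153648693,0.00400137883393792,0,0,63.1760730671321,0.0044313149962139,
1,0.602385592608546,59.524763612728,0.00575705191411227,0,0,58.6995355176343,0.00498788525204181,
1.25,0.643168172396739,60.7174158626165,0.00744219097496998,0,0,49.0656910894307,0.00528091439211596,
1.5,0.739248649970835,59.3907634481462,0.0093389185663757,0,0,43.5355167678091,0.00597779283375681,
1.75,0.823167340070115,57.8885468353601,0.0121724748125673,0,0,38.5783714460239,0.00657460920212243,
2,0.905316227579302,59.3659276875068,0.014043821178424,0,0,32.5277933788846,0.00691644484789019,
2.25,0.974432410333687,55.7494765992286,0.0167435851972465,0,0,26.95608261335,0.00840904361696697,
2.5,1.13723821648928,61.2875057682985,0.0197579501056903,0,0,22.5151321716827,0.00885201102426568,
2.75,1.21525281998306,58.7012503201856,0.0236139903101803,0,0,18.4868628318986,0.00996412454249161,
3,1.30294416279451,62.1072053145573,0.0266995653259543,0,0,16.1032615945932,0.0110806933362096,
3.25,1.37277387048116,58.7526238985675,0.0307509960352991,0,0,12.7295036988114,0.0118765034595243,
3.5,1.67698880710786,56.4098719513037,0.0345233521748456,0,0,9.63900624438983,0.0130310988444415,
3.75,1.78945618313314,58.3552009010465,0.0397666157352478,0,0,7.72469548642107,0.0149233026914928,
4,1.97936061698661,55.3606415473028,0.0456737407957893,0,0,5.47429989389078,0.0155655790140571,
4.25,2.25143589682374,54.4468607810135,0.0506958666614813,0,0,4.04320500244616,0.0188267790852106,
4.5,2.47908754188252,56.5828800134739,0.0591748056319953,0,0,2.34885266729317,0.0193934817702849,
4.75,2.72119875851099,54.8668521522409,0.0626574763418348,0,0,1.23799295939726,0.0227779792799379,
5,3.03685545898567,55.0623952367015,0.0743673758261456,0,0,0,0.0250725747491217,
5.25,3.34249750209897,54.5846325904076,0.0789270761797637,0,0,0,0.0265410357388727,
5.5,3.61646097683658,52.8597473382886,0.0917229148166255,0,0,0,0.0297673094656941,
5.75,3.70142182675725,52.1906120186239,0.151660174054125,0.0307249680511993,0.0231084299469434,0,0.0195596607280867,
6,4.21847945029605,52.1462820177101,0.326552732181353,0.132924404840742,0.0980815350926968,0,0.00563766002312224,
6.25,4.35663804416283,53.4439344646221,0.520677531481888,0.259117349106109,0.176496850323197,0,0.0222436957614894,
6.5,4.57776706358174,48.5092078239038,0.680102428478039,0.354167737513085,0.267140915231349,0,0.00706727447297717,
6.75,4.63794557349212,50.819796261062,0.963131524825684,0.494471238253804,0.362196504867456,0,0.0227875658066787,
7,5.0356513231362,49.5135460203337,1.09442463836543,0.611290867588852,0.412238138611893,0,0.00850238212757812,
7.25,5.45165689392687,49.6295666414346,1.36399752072917,0.764570680311885,0.550534022743636,0,0.0247859175098932,
7.5,5.90993818845911,46.6438680109635,1.57466422286367,0.946281942706754,0.651840705380746,0,0.0108175291856059,
7.75,5.96137532860579,46.5302895243622,1.84463093081325,1.10287592061496,0.74397665978582,0,0.0263298020295741,
8,6.3758134663518,45.2664689135704,2.29842428180401,1.19993207253225,0.893498317443128,0,0.0124356093285384,
8.25,6.63109775514477,43.0280252423837,2.44721614463252,1.28934531015773,0.977924305612957,0,0.0277300204872831,
8.5,6.71659719536434,44.0672753599463,2.64438202869664,1.68010361340968,1.10748283279128,0,0.0149271307022913,
8.75,7.28587189134328,42.6574420180876,2.91988430507076,1.78175342547045,1.28400259733863,0,0.0324213950253909,
9,7.68336893341323,40.6724096599389,3.4493615977513,1.97601471777956,1.46682228619531,0,0.0179695996837862,
9.25,8.17928837328763,40.2529590588887,3.75505891628915,2.15171574631866,1.55494864569634,0,0.0346162477762257,
9.5,8.92518889579318,37.4816443010026,4.09106934364327,2.40877658657099,1.6783845428263,0,0.0188407333506008,
9.75,9.31172423077529,33.9296050718542,4.39918165792628,2.5908591413663,1.8002572642529,0,0.0372097324657224,
10,9.54435189320061,32.9901810538875,4.72251697232543,2.883759845894,2.02025439546479,0,0.0232951169353945,
10.25,10.0320504379542,30.6334400126613,5.20419798699941,3.06763909853341,2.16279130754235,0,0.039470555328675,
10.5,10.8784998629956,29.4790847774704,6.01275869255383,3.23971440712206,2.40005389988709,0,0.0265026029499243,
10.75,11.4167353598699,27.4057640785035,6.20355059151027,3.77127690907341,2.65458711867774,0,0.0423507845998495,
11,11.5909674724939,25.8662219295025,6.55366169956618,4.14689968059763,2.76738873645604,0,0.0307515910893422,aeration_stop
11.25,11.8480591716889,23.4998038723963,8.46251632188504,4.32997269729893,3.15274030956253,0,-0.114458801071347,
11.5,12.5136387784586,22.5361120125767,9.31533340358543,4.61104920547598,3.00051330173831,0,0.0268910996658942,
11.75,12.9543929595339,20.267382345323,10.3464160354079,5.31602273104073,3.16838599460042,0,-0.116287364528231,
12,12.9037055780906,19.8960058955155,12.0485021083361,5.64366426418793,2.9323889663302,0,0.0272453206485726,
12.25,13.5964868544327,17.3974944649391,13.3006997836359,5.78891442253704,3.29296034118883,0,-0.11846269628357,
12.5,13.7058759608852,15.5633755433884,13.9981741898468,6.55496294756998,3.17435883780712,0,0.0245590269563174,
12.75,13.5994246948576,13.3713507152258,16.666319407189,6.89017483719004,3.48034706237162,0,-0.125341030014444,
13,14.3122446761916,11.830307903997,16.8390345798403,7.42312359308865,3.51269916309846,0,0.0218024347190572,
13.25,14.0063511348458,9.05908242074445,17.6003124430684,7.71570609992557,3.51507503385891,0,-0.122804155932789,
13.5,15.4694203638732,7.07424468810748,19.7151299349697,8.95948011550428,3.79538521507044,0,0.019164604319193,
13.75,16.083321259297,5.28773422327823,21.3981904831902,8.90998833486197,3.66109451520314,0,-0.129327003356945,
14,15.3308936575871,2.85370414750543,24.3950317340395,9.07402252465798,3.76614826958775,0,0.0165014808819981,
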